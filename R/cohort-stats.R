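#' Two-sample t-test from printed summary statistics
#'
#' Recomputes a two-sample t-test from `(mean, SD, n)` triples as printed
#' in clinical tables, e.g. birth weights of the larger and smaller twin.
#' The pooled-variance variant uses
#' \deqn{t = \frac{\bar x_1 - \bar x_2}{s_p \sqrt{1/n_1 + 1/n_2}},\quad
#'   s_p^2 = \frac{(n_1-1) s_1^2 + (n_2-1) s_2^2}{n_1 + n_2 - 2},}
#' with \eqn{n_1 + n_2 - 2} degrees of freedom; the Welch variant uses
#' per-group variances with Satterthwaite degrees of freedom. The p-value
#' is two-sided.
#'
#' @param mean1,sd1,n1 Summary statistics of the first group.
#' @param mean2,sd2,n2 Summary statistics of the second group.
#' @param variant `"pooled"` (default) or `"welch"`.
#'
#' @return A one-row tibble with `statistic` (t), `df`, `p.value`,
#'   `estimate` (mean difference) and `method`.
#' @export
#' @examples
#' # sFGR-group birth weights, larger vs smaller twin (g):
#' t_from_summary(2119, 454, 23, 1444, 350, 23)
t_from_summary <- function(mean1, sd1, n1, mean2, sd2, n2,
                           variant = c("pooled", "welch")) {
  variant <- match.arg(variant)
  check_number(mean1, "mean1"); check_number(mean2, "mean2")
  check_number(sd1, "sd1", min = 0); check_number(sd2, "sd2", min = 0)
  check_number(n1, "n1", min = 2); check_number(n2, "n2", min = 2)

  diff <- mean1 - mean2
  if (variant == "pooled") {
    df <- n1 + n2 - 2
    sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / df
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  } else {
    v1 <- sd1^2 / n1
    v2 <- sd2^2 / n2
    se <- sqrt(v1 + v2)
    df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  }
  stat <- if (se > 0) diff / se else 0
  tibble(
    statistic = stat,
    df = df,
    p.value = 2 * pt(-abs(stat), df),
    estimate = diff,
    method = paste0("Two-sample t (", variant, ") from summary statistics")
  )
}

#' Percentage as printed in count(percent) table cells
#'
#' `100 * count / total`, rounded half-up to one decimal place — the
#' rounding convention of printed clinical tables (so 23/32 prints 71.9,
#' not 71.8).
#'
#' @param count Numerator count, `0 <= count <= total`.
#' @param total Positive denominator.
#'
#' @return Percentage with one decimal place.
#' @export
#' @examples
#' proportion_pct(19, 23)  # 82.6
#' proportion_pct(23, 32)  # 71.9
proportion_pct <- function(count, total) {
  check_number(count, "count", min = 0)
  check_number(total, "total", min = 0, strict_min = TRUE)
  if (count > total) stop_invalid("`count` must not exceed `total`.")
  round_half_up(100 * count / total, 1)
}

#' Rank-sum (Mann-Whitney) Z statistic
#'
#' Wilcoxon rank-sum comparison of two samples reported as a
#' normal-approximation Z with tie correction:
#' \deqn{Z = \frac{U - n_1 n_2 / 2}{\sigma_U},\qquad
#'   \sigma_U^2 = \frac{n_1 n_2}{12}\left(n + 1 -
#'     \frac{\sum_j (t_j^3 - t_j)}{n (n - 1)}\right),}
#' with \eqn{n = n_1 + n_2} and \eqn{t_j} the size of the j-th group of
#' ties. No continuity correction is applied, so \eqn{Z} equals the
#' observed U standardised by the exact mean and standard deviation of its
#' permutation distribution. The p-value is two-sided.
#'
#' @param x,y Numeric samples (non-empty).
#'
#' @return A one-row tibble with `statistic` (Z, signed: positive when `x`
#'   tends to exceed `y`), `p.value`, `u` and `method`.
#' @export
#' @examples
#' rank_sum_z(c(1, 2, 3), c(4, 5, 6))
rank_sum_z <- function(x, y) {
  if (length(x) == 0 || length(y) == 0) {
    stop_invalid("Both samples must be non-empty.")
  }
  if (anyNA(x) || anyNA(y)) stop_invalid("Samples must not contain NA.")
  n1 <- length(x)
  n2 <- length(y)
  n <- n1 + n2
  r <- rank(c(x, y))
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2  # U for x over y
  mu <- n1 * n2 / 2
  ties <- table(c(x, y))
  tie_term <- sum(ties^3 - ties)
  sigma2 <- n1 * n2 / 12 * ((n + 1) - tie_term / (n * (n - 1)))
  if (sigma2 <= 0) {
    z <- 0  # all observations tied: no evidence either way
  } else {
    z <- (u - mu) / sqrt(sigma2)
  }
  tibble(
    statistic = z,
    p.value = 2 * pnorm(-abs(z)),
    u = u,
    method = "Mann-Whitney rank-sum Z (normal approximation, tie-corrected)"
  )
}

#' Fisher's exact or chi-square test for a 2x2 table
#'
#' Group comparisons of categorical "general condition" counts. The test
#' is chosen by the standard small-expected-count rule: Fisher's exact
#' two-sided test when any expected cell count is below 5, otherwise the
#' chi-square test with continuity correction. The rule can be overridden
#' with `method`.
#'
#' @param table_2x2 A 2x2 matrix (or coercible) of non-negative integer
#'   counts.
#' @param method `"auto"` (default, the expected-count rule), `"fisher"`
#'   or `"chisq"`.
#'
#' @return A one-row tibble with `p.value`, `statistic` (chi-square
#'   statistic, `NA` for Fisher), `method` and `min_expected`.
#' @export
#' @examples
#' fisher_exact_or_chisq(matrix(c(1, 3, 22, 29), 2))
fisher_exact_or_chisq <- function(table_2x2, method = c("auto", "fisher",
                                                        "chisq")) {
  method <- match.arg(method)
  m <- as.matrix(table_2x2)
  if (!all(dim(m) == c(2L, 2L))) stop_invalid("`table_2x2` must be 2x2.")
  if (anyNA(m) || any(m < 0) || any(m != round(m))) {
    stop_invalid("Cells must be non-negative integers.")
  }
  expected <- outer(rowSums(m), colSums(m)) / sum(m)
  min_exp <- min(expected)
  if (method == "auto") {
    method <- if (min_exp < 5) "fisher" else "chisq"
  }
  if (method == "fisher") {
    ft <- fisher.test(m)
    tibble(p.value = ft$p.value, statistic = NA_real_,
           method = "Fisher exact (two-sided)", min_expected = min_exp)
  } else {
    ct <- suppressWarnings(chisq.test(m, correct = TRUE))
    tibble(p.value = ct$p.value, statistic = unname(ct$statistic),
           method = "Chi-square with continuity correction",
           min_expected = min_exp)
  }
}
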