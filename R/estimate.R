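#' Estimate heart rate from an autocorrelation via the lookup table
#'
#' Reads the autocorrelation at each serial-number lag of the heart-rate
#' correspondence table, normalises by \eqn{R(0)}, and returns the grid
#' heart rate carrying the maximum. Ties go to the lower heart rate (the
#' longer period — fundamental over harmonic). The normalised peak value is
#' reported as the confidence; windows whose confidence falls below
#' `min_confidence` (or whose envelope has no energy at all) report
#' `no_signal` instead of a spurious rate.
#'
#' A harmonic guard protects against locking onto half the true beat
#' period: when the bias-corrected autocorrelation at twice the winning lag
#' clearly exceeds the winner's bias-corrected value, the doubled lag
#' (halved rate) is preferred.
#'
#' @param autocorr An `autocorr_result` from [autocorrelate()]; must cover
#'   every lag in the table.
#' @param table An `hr_lookup` from [build_lookup()].
#' @param min_confidence Minimum normalised peak value to accept (default
#'   0.3).
#'
#' @return A one-row tibble with columns `bpm`, `confidence` (in `[0, 1]`)
#'   and `status` (`"normal"`, `"distress"` or `"no_signal"`); `bpm` is `NA`
#'   when the status is `no_signal`.
#' @export
estimate_hr <- function(autocorr, table, min_confidence = 0.3) {
  stopifnot(inherits(table, "hr_lookup"))
  sn <- table$serial_number
  max_lag <- max(autocorr$lag)
  if (max(sn) > max_lag) {
    stop_insufficient(sprintf(
      "Table needs lags up to %d but the autocorrelation only covers %d.",
      max(sn), max_lag))
  }
  r <- autocorr$value
  n_win <- attr(autocorr, "window_len")
  r0 <- r[1L]
  if (!is.finite(r0) || r0 <= 0) {
    return(fhr_estimate(NA_real_, 0, "no_signal"))
  }

  norm <- r[sn + 1L] / r0
  idx <- which.max(norm)  # first max = lowest heart rate on ties

  # Harmonic (half-period) guard: only switch to the doubled lag when its
  # bias-corrected value clearly beats the winner's; a plain near-equality
  # rule would mis-halve genuinely fast rates, because for a periodic
  # envelope the biased R at twice the period is only a factor
  # (N - 2P)/(N - P) below the peak.
  lag_win <- sn[idx]
  lag_dbl <- 2L * lag_win
  if (!is.null(n_win) && lag_dbl <= max_lag && lag_dbl < n_win) {
    corr_win <- r[lag_win + 1L] / (1 - lag_win / n_win)
    corr_dbl <- r[lag_dbl + 1L] / (1 - lag_dbl / n_win)
    if (is.finite(corr_dbl) && corr_dbl > 1.05 * corr_win) {
      j <- which.min(abs(sn - lag_dbl))
      if (abs(sn[j] - lag_dbl) <= max(1, 0.02 * lag_dbl)) idx <- j
    }
  }

  bpm <- table$hr_bpm[idx]
  confidence <- min(1, max(0, norm[idx]))
  if (confidence < min_confidence) {
    return(fhr_estimate(NA_real_, confidence, "no_signal"))
  }
  fhr_estimate(bpm, confidence, classify_fhr(bpm))
}

#' Estimate heart rate by the average magnitude difference function
#'
#' Minimum-seeking alternative to the autocorrelation maximum search: the
#' average magnitude difference
#' \deqn{D(m) = \frac{1}{N-m} \sum_{n=0}^{N-1-m} |x(n) - x(n+m)|}
#' is evaluated at the table's serial-number lags and the heart rate
#' minimising it is returned. For a periodic envelope the difference nearly
#' vanishes at the true period *and* at its integer multiples, so the raw
#' argmin can land on a subharmonic; among all lags whose difference is
#' within 3% of the observed range of the minimum, the smallest lag — the
#' fundamental period — wins. Confidence is `1 - D(S*)/max(D)` over the
#' table lags.
#'
#' @param envelope A `doppler_envelope` (or data frame with a `value`
#'   column) covering at least `max(serial_number) + 1` samples.
#' @inheritParams estimate_hr
#'
#' @return A one-row tibble as for [estimate_hr()].
#' @export
estimate_hr_amdf <- function(envelope, table, min_confidence = 0.3) {
  stopifnot(inherits(table, "hr_lookup"))
  x <- envelope$value
  if (is.null(x)) stop_invalid("`envelope` must have a `value` column.")
  sn <- table$serial_number
  if (max(sn) >= length(x)) {
    stop_insufficient(sprintf(
      "Table needs lags up to %d but the envelope has only %d samples.",
      max(sn), length(x)))
  }
  d <- amdf_at(x - mean(x), sn)
  dmax <- max(d)
  if (!is.finite(dmax) || dmax <= 0) {
    return(fhr_estimate(NA_real_, 0, "no_signal"))
  }
  dmin <- min(d)
  near <- which(d <= dmin + 0.03 * (dmax - dmin))
  idx <- near[which.min(sn[near])]  # fundamental: smallest near-minimal lag
  confidence <- 1 - d[idx] / dmax
  if (confidence < min_confidence) {
    return(fhr_estimate(NA_real_, confidence, "no_signal"))
  }
  fhr_estimate(table$hr_bpm[idx], confidence, classify_fhr(table$hr_bpm[idx]))
}

fhr_estimate <- function(bpm, confidence, status) {
  tibble(bpm = bpm, confidence = confidence, status = status)
}

#' Classify a fetal heart rate as normal or distress
#'
#' A normal fetal heart rate lies between 120 and 160 beats per minute
#' (boundaries inclusive); rates outside that band indicate fetal distress.
#'
#' @param bpm Heart rate(s) in beats per minute; must be positive.
#'
#' @return Character vector: `"normal"` or `"distress"`.
#' @export
#' @examples
#' classify_fhr(c(110, 120, 140, 160, 161))
classify_fhr <- function(bpm) {
  if (!is.numeric(bpm) || anyNA(bpm) || any(bpm <= 0)) {
    stop_invalid("`bpm` must be positive.")
  }
  ifelse(bpm >= 120 & bpm <= 160, "normal", "distress")
}
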