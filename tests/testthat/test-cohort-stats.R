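test_that("pooled t from summaries reproduces hand arithmetic and table values", {
  # printed birth weights, larger vs smaller twin of the sFGR group
  res <- t_from_summary(2119, 454, 23, 1444, 350, 23)
  expect_lt(abs(res$statistic - 5.642), 0.02)
  expect_identical(res$df, 44)
  expect_lt(res$p.value, 0.0005)  # printed as 0.000

  expect_equal(t_from_summary(10, 1, 5, 8, 1, 5)$statistic,
               2 * sqrt(5) / sqrt(2), tolerance = 1e-12)
  expect_equal(t_from_summary(7, 2, 9, 7, 2, 9)$statistic, 0)
  expect_error(t_from_summary(1, 1, 1, 2, 1, 5),
               class = "fhrdoppler_invalid_parameter")
})

test_that("summary t equals the raw-data t.test on random fixtures", {
  set.seed(5)
  for (i in 1:20) {
    x <- rnorm(sample(5:30, 1), mean = runif(1, -2, 2), sd = runif(1, 0.5, 3))
    y <- rnorm(sample(5:30, 1), mean = runif(1, -2, 2), sd = runif(1, 0.5, 3))
    got_p <- t_from_summary(mean(x), sd(x), length(x),
                            mean(y), sd(y), length(y), variant = "pooled")
    ref_p <- t.test(x, y, var.equal = TRUE)
    expect_equal(got_p$statistic, unname(ref_p$statistic), tolerance = 1e-9)
    expect_equal(got_p$p.value, ref_p$p.value, tolerance = 1e-9)

    got_w <- t_from_summary(mean(x), sd(x), length(x),
                            mean(y), sd(y), length(y), variant = "welch")
    ref_w <- t.test(x, y)
    expect_equal(got_w$statistic, unname(ref_w$statistic), tolerance = 1e-9)
    expect_equal(got_w$df, unname(ref_w$parameter), tolerance = 1e-9)
  }
})

test_that("percentages round half-up to one decimal like printed tables", {
  expect_identical(proportion_pct(19, 23), 82.6)
  expect_identical(proportion_pct(23, 32), 71.9)  # 71.875 rounds up
  expect_identical(proportion_pct(0, 23), 0)
  expect_error(proportion_pct(5, 0), class = "fhrdoppler_invalid_parameter")
  expect_error(proportion_pct(6, 5), class = "fhrdoppler_invalid_parameter")
  set.seed(2)
  for (i in 1:50) {
    n <- sample(1:100, 1); k <- sample(0:n, 1)
    expect_lt(abs(proportion_pct(k, n) + proportion_pct(n - k, n) - 100),
              0.1 + 1e-9)
  }
})

test_that("rank-sum Z standardises U by its exact permutation moments", {
  res <- rank_sum_z(c(1, 2, 3), c(4, 5, 6))
  expect_identical(res$u, 0)
  expect_equal(abs(res$statistic), abs(perm_z_oracle(c(1, 2, 3), c(4, 5, 6))),
               tolerance = 1e-9)
  expect_equal(rank_sum_z(c(1, 2, 3), c(1, 2, 3))$statistic, 0)
  expect_error(rank_sum_z(numeric(0), 1:3),
               class = "fhrdoppler_invalid_parameter")

  set.seed(8)
  for (i in 1:15) {
    n1 <- sample(2:6, 1); n2 <- sample(2:6, 1)
    # ties included: sample from a small integer support
    x <- sample(1:5, n1, replace = TRUE)
    y <- sample(1:5, n2, replace = TRUE)
    if (length(unique(c(x, y))) < 2) next
    expect_equal(abs(rank_sum_z(x, y)$statistic),
                 abs(perm_z_oracle(x, y)), tolerance = 1e-9)
  }
})

test_that("shifting one sample away never decreases |Z|", {
  set.seed(13)
  x <- rnorm(5); y <- rnorm(5)
  z0 <- abs(rank_sum_z(x, y)$statistic)
  z_shift <- abs(rank_sum_z(x, y + 100)$statistic)
  expect_gte(z_shift, z0 - 1e-12)
  # and the fully separated case attains the maximum over permutations
  expect_equal(z_shift, abs(perm_z_oracle(x, y + 100)), tolerance = 1e-9)
})

test_that("2x2 comparisons use Fisher below the expected-count rule", {
  m <- matrix(c(1, 3, 22, 29), 2, byrow = FALSE)
  res <- fisher_exact_or_chisq(m)
  expect_match(res$method, "Fisher")
  expect_equal(res$p.value, fisher_p_oracle(m), tolerance = 1e-9)

  same <- matrix(c(10, 10, 5, 5), 2)
  expect_equal(fisher_exact_or_chisq(same, method = "fisher")$p.value, 1,
               tolerance = 1e-9)

  m2 <- matrix(c(0, 1, 23, 31), 2)
  expect_equal(fisher_exact_or_chisq(m2)$p.value, fisher_p_oracle(m2),
               tolerance = 1e-9)
  expect_equal(fisher_exact_or_chisq(m2)$p.value, 1, tolerance = 1e-9)

  big <- matrix(c(30, 28, 25, 27), 2)
  expect_match(fisher_exact_or_chisq(big)$method, "Chi-square")
  expect_equal(fisher_exact_or_chisq(big)$p.value,
               suppressWarnings(chisq.test(big)$p.value), tolerance = 1e-12)
  expect_error(fisher_exact_or_chisq(matrix(c(-1, 2, 3, 4), 2)),
               class = "fhrdoppler_invalid_parameter")
})

test_that("cohort tables drive the summary operations coherently", {
  tabs <- twin_cohort_tables()
  bw <- tabs$birthweight
  sfgr <- bw[bw$group == "sFGR", ]
  res <- t_from_summary(sfgr$mean_g[1], sfgr$sd_g[1], sfgr$n[1],
                        sfgr$mean_g[2], sfgr$sd_g[2], sfgr$n[2])
  expect_lt(abs(res$statistic - 5.642), 0.02)
  av <- tabs$av_anastomosis
  expect_identical(proportion_pct(av$count[1], av$n[1]), 82.6)
  expect_identical(proportion_pct(av$count[2], av$n[2]), 71.9)
  gc <- tabs$general_conditions
  ps <- vapply(seq_len(nrow(gc)), function(i) {
    m <- matrix(c(gc$sfgr_count[i], gc$sfgr_n[i] - gc$sfgr_count[i],
                  gc$control_count[i], gc$control_n[i] - gc$control_count[i]),
                2, byrow = TRUE)
    fisher_exact_or_chisq(m)$p.value
  }, numeric(1))
  expect_true(all(ps > 0.05))  # none of the general conditions differ
})
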