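test_that("demodulation maps zero signals to zero envelopes and checks cutoffs", {
  z <- doppler_signal(numeric(4000), 4000)
  env <- demodulate(z)
  expect_true(all(env$value == 0))
  expect_error(demodulate(z, cutoff_hz = 3000),
               class = "fhrdoppler_invalid_parameter")
  expect_error(demodulate(z, decimate_to_hz = 8000),
               class = "fhrdoppler_invalid_parameter")
})

test_that("a stationary tone demodulates to a near-constant envelope", {
  fs <- 4000
  t <- (0:(4 * fs - 1)) / fs
  tone <- doppler_signal(sin(2 * pi * 300 * t), fs)
  env <- demodulate(tone, cutoff_hz = 20)
  cv <- sd(env$value) / mean(env$value)
  expect_lt(cv, 0.05)
})

test_that("envelope of a 120 bpm signal has its spectral peak at 2 Hz", {
  sig <- synthesize_doppler(doppler_config(heart_rate_bpm = 120,
                                           duration_s = 8))
  env <- demodulate(sig)
  fs <- sample_rate(env)
  x <- env$value - mean(env$value)
  spec <- Mod(fft(x))^2
  freqs <- (seq_along(x) - 1) * fs / length(x)
  keep <- freqs > 0.5 & freqs < 10
  peak <- freqs[keep][which.max(spec[keep])]
  expect_lt(abs(peak - 2), fs / length(x) + 1e-9)  # within one bin
})

test_that("autocorrelation matches the literal double-loop estimator", {
  set.seed(1)
  for (i in 1:10) {
    n <- sample(50:400, 1)
    x <- rnorm(n)
    ml <- sample(5:min(40, n - 1), 1)
    got <- autocorrelate(tibble::tibble(value = x), max_lag = ml)
    want <- naive_autocorr(x, ml)
    expect_equal(got$value, want, tolerance = 1e-9)
    expect_true(all(got$value[1] >= got$value))  # biased: R(0) is max
  }
})

test_that("autocorrelation degenerate and error cases", {
  flat <- autocorrelate(tibble::tibble(value = rep(3, 100)), max_lag = 10)
  expect_true(all(flat$value == 0))
  expect_error(autocorrelate(tibble::tibble(value = rnorm(10)), max_lag = 10),
               class = "fhrdoppler_insufficient_data")
  x <- impulse_train(25, 500)
  ac <- autocorrelate(tibble::tibble(value = x), max_lag = 60)
  expect_identical(ac$lag[-1][which.max(ac$value[-1])], 25L)
})

test_that("lookup table implements round(60*fs/hr) with duplicate collapse", {
  tab <- build_lookup(1000, 50, 240)
  expect_identical(tab$serial_number[tab$hr_bpm == 120], 500L)
  expect_identical(tab$serial_number[tab$hr_bpm == 60], 1000L)
  expect_true(all(diff(tab$serial_number) < 0))   # strictly decreasing
  expect_true(all(diff(tab$hr_bpm) > 0))
  # product invariant: hr * serial ~ 60*fs within rounding
  expect_true(all(abs(tab$hr_bpm * tab$serial_number - 60 * 1000)
                  <= tab$hr_bpm / 2))
  tab200 <- build_lookup(200, 50, 240)
  expect_true(all(abs(tab200$hr_bpm * tab200$serial_number - 60 * 200)
                  <= tab200$hr_bpm / 2))
  expect_error(build_lookup(1, 50, 240),
               class = "fhrdoppler_invalid_parameter")
  expect_error(build_lookup(200, 240, 50),
               class = "fhrdoppler_invalid_parameter")
})

test_that("lookup-table search finds the rate of a periodic envelope", {
  fs <- 200
  tab <- build_lookup(fs, 50, 240)
  x <- impulse_train(100, 1600)  # 2 Hz -> 120 bpm
  ac <- autocorrelate(as_envelope(x, fs), max_lag = max(tab$serial_number))
  est <- estimate_hr(ac, tab)
  expect_identical(est$bpm, 120)
  expect_identical(est$status, "normal")
  expect_true(est$confidence > 0.3 && est$confidence <= 1)

  zero <- autocorrelate(as_envelope(numeric(1600), fs),
                        max_lag = max(tab$serial_number))
  expect_identical(estimate_hr(zero, tab)$status, "no_signal")

  short <- autocorrelate(as_envelope(x, fs), max_lag = 100)
  expect_error(estimate_hr(short, tab),
               class = "fhrdoppler_insufficient_data")
})

test_that("lookup search agrees with the exhaustive full-lag argmax", {
  fs <- 500
  tab <- build_lookup(fs, 50, 240)
  max_sn <- max(tab$serial_number)
  set.seed(11)
  for (i in 1:25) {
    period <- runif(1, 130, 590)
    x <- pulse_train(period, 2400)
    ac <- autocorrelate(as_envelope(x, fs), max_lag = max_sn)
    est <- estimate_hr(ac, tab)
    want <- exhaustive_hr(ac, fs, 50, 240)
    expect_lt(abs(est$bpm - want), 1 + 1e-9)
  }
})

test_that("AMDF search recovers periodic envelopes and matches autocorrelation", {
  fs <- 200
  tab <- build_lookup(fs, 50, 240)
  x <- impulse_train(80, 1600)  # 150 bpm
  est <- estimate_hr_amdf(as_envelope(x, fs), tab)
  expect_identical(est$bpm, 150)
  expect_identical(estimate_hr_amdf(as_envelope(numeric(1600), fs),
                                    tab)$status, "no_signal")

  # cross-method consistency on noiseless simulated signals
  for (hr in c(70, 110, 150, 200)) {
    sig <- synthesize_doppler(doppler_config(heart_rate_bpm = hr,
                                             duration_s = 8))
    a <- tidy(track(sig, method = "autocorr"))$bpm
    b <- tidy(track(sig, method = "amdf"))$bpm
    expect_true(all(abs(a - b) <= 1))
  }
})

test_that("heart-rate status thresholds sit exactly at 120 and 160 bpm", {
  expect_identical(classify_fhr(140), "normal")
  expect_identical(classify_fhr(110), "distress")
  expect_identical(classify_fhr(c(120, 160)), c("normal", "normal"))
  expect_identical(classify_fhr(c(119.9, 160.1)), c("distress", "distress"))
  expect_error(classify_fhr(0), class = "fhrdoppler_invalid_parameter")
  grid <- seq(50, 240, by = 0.5)
  st <- classify_fhr(grid)
  expect_identical(st == "normal", grid >= 120 & grid <= 160)
})

test_that("tracking recovers a constant rate and handles short signals", {
  sig <- synthesize_doppler(doppler_config(heart_rate_bpm = 150,
                                           duration_s = 8))
  est <- tidy(track(sig))
  expect_true(all(abs(est$bpm - 150) <= 1))
  expect_true(all(est$status == "normal"))

  one <- synthesize_doppler(doppler_config(heart_rate_bpm = 150,
                                           duration_s = 4))
  est1 <- tidy(track(one))
  expect_identical(nrow(est1), 1L)
  expect_identical(est1$bpm, est1$bpm_raw)  # no smoothing on one window

  tiny <- synthesize_doppler(doppler_config(heart_rate_bpm = 150,
                                            duration_s = 2))
  expect_error(track(tiny), class = "fhrdoppler_insufficient_data")
})

test_that("a mid-signal rate step produces a monotone transition", {
  s1 <- synthesize_doppler(doppler_config(heart_rate_bpm = 120,
                                          duration_s = 6))
  s2 <- synthesize_doppler(doppler_config(heart_rate_bpm = 160,
                                          duration_s = 6))
  sig <- doppler_signal(c(s1$amplitude, s2$amplitude), 4000)
  est <- tidy(track(sig))
  before <- est$bpm[est$window_start_s + 4 <= 6]
  after <- est$bpm[est$window_start_s >= 6]
  expect_true(all(abs(before - 120) <= 2))
  expect_true(all(abs(after - 160) <= 2))
  expect_true(all(diff(est$bpm) >= -2))  # monotone up to grid jitter
})
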