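# Independent oracles used across the suite. These deliberately use the
# slowest, most literal formulation (scalar double loops, full enumeration)
# so they share no code path with the package implementation.

# Biased autocorrelation of the mean-removed vector, literal double loop.
naive_autocorr <- function(x, max_lag) {
  x <- x - mean(x)
  n <- length(x)
  vals <- numeric(max_lag + 1)
  for (m in 0:max_lag) {
    s <- 0
    for (i in seq_len(n - m)) s <- s + x[i] * x[i + m]
    vals[m + 1] <- s / n
  }
  vals
}

# Exact permutation mean/sd of the Mann-Whitney U and the standardized
# observed U, by full enumeration of group assignments.
perm_z_oracle <- function(x, y) {
  n1 <- length(x)
  pooled <- c(x, y)
  r <- rank(pooled)
  u_of <- function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2
  combos <- utils::combn(length(pooled), n1)
  us <- apply(combos, 2, u_of)
  u_obs <- u_of(seq_len(n1))
  (u_obs - mean(us)) / sqrt(mean((us - mean(us))^2))
}

# Two-sided Fisher p by explicit hypergeometric enumeration over all
# tables with the observed margins.
fisher_p_oracle <- function(m) {
  r1 <- sum(m[1, ]); c1 <- sum(m[, 1]); n <- sum(m)
  lo <- max(0, r1 - (n - c1)); hi <- min(r1, c1)
  a_all <- lo:hi
  probs <- stats::dhyper(a_all, c1, n - c1, r1)
  p_obs <- stats::dhyper(m[1, 1], c1, n - c1, r1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Unit impulse train of given integer period.
impulse_train <- function(period, n) {
  x <- numeric(n)
  x[seq(1, n, by = period)] <- 1
  x
}

# Noiseless beat-envelope fixture: raised-cosine pulse train (pulse width
# 30% of the cycle), period may be fractional.
pulse_train <- function(period, n, width_frac = 0.3) {
  phase <- ((0:(n - 1)) %% period) / period
  ifelse(phase < width_frac,
         0.5 * (1 - cos(2 * pi * phase / width_frac)), 0)
}

# Envelope-like object around a bare vector.
as_envelope <- function(x, fs) {
  e <- tibble::tibble(time_s = (seq_along(x) - 1) / fs, value = x)
  class(e) <- c("doppler_envelope", class(e))
  attr(e, "sample_rate_hz") <- fs
  e
}

# All permutations of a short vector.
all_perms <- function(v) {
  if (length(v) <= 1) return(list(v))
  unlist(lapply(seq_along(v), function(i) {
    lapply(all_perms(v[-i]), function(p) c(v[i], p))
  }), recursive = FALSE)
}

# Full-lag search oracle: heart rate from the exhaustive argmax of the
# autocorrelation over the whole candidate lag range.
exhaustive_hr <- function(ac, fs, hr_min, hr_max) {
  lag_lo <- max(1L, floor(60 * fs / hr_max))
  lag_hi <- ceiling(60 * fs / hr_min)
  lags <- lag_lo:min(lag_hi, max(ac$lag))
  m_star <- lags[which.max(ac$value[lags + 1])]
  60 * fs / m_star
}
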