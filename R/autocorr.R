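#' Windowed autocorrelation estimate of an envelope
#'
#' Biased autocorrelation estimator over a window of \eqn{N} samples,
#' computed on the mean-removed envelope:
#' \deqn{R(m) = \frac{1}{N} \sum_{n=0}^{N-1-m} x(n)\,x(n+m),
#'   \quad m = 0, \dots, m_{max}.}
#' The \eqn{1/N} (rather than \eqn{1/(N-m)}) normalisation guarantees
#' \eqn{R(0) \ge R(m)} for every lag, which the peak-normalised confidence
#' of the heart-rate search relies on. The periodic peaks of \eqn{R} encode
#' the heart period in lag units.
#'
#' @param envelope A `doppler_envelope` (see [demodulate()]) or any data
#'   frame with a `value` column; the window is the whole input.
#' @param max_lag Largest lag \eqn{m_{max}} to evaluate; must be smaller
#'   than the window length.
#'
#' @return A tibble of class `autocorr_result` with columns `lag`
#'   (0..`max_lag`) and `value`, and attributes `window_len` (\eqn{N}) and
#'   `sample_rate_hz` (carried from the envelope when present).
#' @export
#' @examples
#' x <- rep(c(1, 0, 0, 0), 50)  # impulse train, period 4
#' ac <- autocorrelate(tibble::tibble(value = x), max_lag = 10)
#' ac$lag[-1][which.max(ac$value[-1])]  # 4
autocorrelate <- function(envelope, max_lag) {
  x <- envelope$value
  if (is.null(x)) stop_invalid("`envelope` must have a `value` column.")
  n <- length(x)
  check_number(max_lag, "max_lag", min = 0)
  max_lag <- as.integer(max_lag)
  if (n < max_lag + 1L) {
    stop_insufficient(sprintf(
      "Window of %d samples is too short for max_lag = %d.", n, max_lag))
  }
  x <- x - mean(x)
  vals <- vapply(0:max_lag, function(m) {
    sum(x[seq_len(n - m)] * x[seq_len(n - m) + m]) / n
  }, numeric(1))
  out <- tibble(lag = 0:max_lag, value = vals)
  class(out) <- c("autocorr_result", class(out))
  attr(out, "window_len") <- n
  attr(out, "sample_rate_hz") <- attr(envelope, "sample_rate_hz")
  out
}

# Average magnitude difference function at selected lags:
# D(m) = (1/(N-m)) * sum |x(n) - x(n+m)|. Minimum-seeking counterpart of
# the autocorrelation maximum search.
amdf_at <- function(x, lags) {
  n <- length(x)
  vapply(lags, function(m) {
    sum(abs(x[seq_len(n - m)] - x[seq_len(n - m) + m])) / (n - m)
  }, numeric(1))
}
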