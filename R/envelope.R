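#' Demodulate a Doppler signal to its beat envelope
#'
#' Full-wave rectification followed by a 4th-order Butterworth low-pass
#' filter (applied forward-backward, so zero phase) and resampling to a
#' reduced envelope rate. The beat envelope at a few hundred Hz is what the
#' windowed autocorrelation operates on; working at a reduced sampling
#' frequency keeps the heart-rate lag table short.
#'
#' @param signal A [doppler_signal()], or a data frame with an `amplitude`
#'   column and a `sample_rate_hz` attribute.
#' @param cutoff_hz Low-pass cutoff in Hz; must be below the signal Nyquist
#'   frequency. Default 10 Hz, comfortably above the 1--4 Hz beat
#'   fundamental.
#' @param decimate_to_hz Envelope sampling rate after resampling (Hz);
#'   must not exceed the signal rate. Default 500 Hz.
#'
#' @return A tibble of class `doppler_envelope` with columns `time_s` and
#'   `value` (non-negative), `sample_rate_hz` attribute equal to
#'   `decimate_to_hz`, and the input's `truth_bpm` attribute carried along.
#' @export
#' @examples
#' sig <- synthesize_doppler(doppler_config(heart_rate_bpm = 120,
#'                                          duration_s = 2, seed = 1))
#' env <- demodulate(sig)
#' range(env$value)
demodulate <- function(signal, cutoff_hz = 10, decimate_to_hz = 500) {
  fs <- sample_rate(signal)
  check_number(cutoff_hz, "cutoff_hz", min = 0, strict_min = TRUE)
  check_number(decimate_to_hz, "decimate_to_hz", min = 0, strict_min = TRUE)
  if (cutoff_hz >= fs / 2) {
    stop_invalid(sprintf(
      "`cutoff_hz` (%g) must be below the Nyquist frequency %g Hz.",
      cutoff_hz, fs / 2))
  }
  if (decimate_to_hz > fs) {
    stop_invalid("`decimate_to_hz` must not exceed the signal sampling rate.")
  }
  x <- signal$amplitude
  if (is.null(x)) stop_invalid("`signal` must have an `amplitude` column.")

  rect <- abs(x)
  bf <- signal::butter(4, cutoff_hz / (fs / 2), type = "low")
  # reflect the rectified signal at both ends before zero-phase filtering,
  # so the filter transient decays inside the padding, not the envelope
  pad <- min(length(rect) - 1L, ceiling(2 * fs / cutoff_hz))
  padded <- c(rev(rect[seq_len(pad)]), rect,
              rev(rect[seq.int(length(rect) - pad + 1L, length(rect))]))
  smooth <- as.numeric(signal::filtfilt(bf, padded))
  smooth <- smooth[(pad + 1L):(pad + length(rect))]

  t_in <- (seq_along(smooth) - 1) / fs
  n_out <- max(1L, floor(t_in[length(t_in)] * decimate_to_hz) + 1L)
  t_out <- (seq_len(n_out) - 1) / decimate_to_hz
  value <- approx(t_in, smooth, xout = t_out, rule = 2)$y
  value <- pmax(value, 0)

  out <- tibble(time_s = t_out, value = value)
  class(out) <- c("doppler_envelope", class(out))
  attr(out, "sample_rate_hz") <- decimate_to_hz
  attr(out, "truth_bpm") <- attr(signal, "truth_bpm")
  out
}
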