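#' Heart-rate / autocorrelation serial-number correspondence table
#'
#' For a candidate heart rate \eqn{R_f} (bpm) and envelope sampling
#' frequency \eqn{f_s}, the beat period in samples is the autocorrelation
#' lag "serial number"
#' \deqn{S_n = \mathrm{round}(60 f_s / R_f).}
#' Precomputing \eqn{S_n} over a heart-rate grid means the autocorrelation
#' only ever needs to be read at those lags: the estimate is the grid rate
#' whose serial-number lag carries the largest autocorrelation value.
#' Rounding is half-up. Grid rates that collapse to the same serial number
#' keep the first (lowest-rate) entry, so serial numbers are strictly
#' decreasing in heart rate.
#'
#' @param sample_rate_hz Envelope sampling frequency \eqn{f_s} in Hz.
#' @param hr_min_bpm,hr_max_bpm Heart-rate search range in bpm
#'   (defaults 50--240).
#' @param step_bpm Grid step in bpm (default 1).
#'
#' @return A tibble of class `hr_lookup` with columns `hr_bpm` (ascending)
#'   and `serial_number` (strictly decreasing), and a `sample_rate_hz`
#'   attribute.
#' @export
#' @examples
#' tab <- build_lookup(1000, 60, 120)
#' tab[tab$hr_bpm == 120, ]  # serial number 500
build_lookup <- function(sample_rate_hz, hr_min_bpm = 50, hr_max_bpm = 240,
                         step_bpm = 1) {
  check_number(sample_rate_hz, "sample_rate_hz", min = 0, strict_min = TRUE)
  check_number(step_bpm, "step_bpm", min = 0, strict_min = TRUE)
  check_number(hr_min_bpm, "hr_min_bpm", min = 0, strict_min = TRUE)
  check_number(hr_max_bpm, "hr_max_bpm", min = 0, strict_min = TRUE)
  if (hr_min_bpm >= hr_max_bpm) {
    stop_invalid("`hr_min_bpm` must be smaller than `hr_max_bpm`.")
  }
  hr <- seq(hr_min_bpm, hr_max_bpm, by = step_bpm)
  sn <- round_half_up(60 * sample_rate_hz / hr)
  if (any(sn < 1)) {
    stop_invalid(sprintf(
      "Sampling rate %g Hz is too low: some serial numbers round below 1.",
      sample_rate_hz))
  }
  keep <- !duplicated(sn)  # first = lowest heart rate per serial number
  out <- tibble(hr_bpm = hr[keep], serial_number = as.integer(sn[keep]))
  class(out) <- c("hr_lookup", class(out))
  attr(out, "sample_rate_hz") <- sample_rate_hz
  out
}
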