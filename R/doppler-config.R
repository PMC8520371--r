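#' Configuration for the synthetic Doppler signal generator
#'
#' Collects the physical and sampling parameters used to synthesize an
#' ultrasound Doppler audio signal with a known ground-truth fetal heart
#' rate. The physical parameters feed the reflected-wave Doppler shift
#' relation \eqn{f_D = 2 v f_0 \cos\theta / c}.
#'
#' @param heart_rate_bpm Ground-truth heart rate in beats per minute
#'   (30--300).
#' @param duration_s Signal duration in seconds.
#' @param snr_db Signal-to-noise ratio of the additive white Gaussian noise,
#'   in dB. `Inf` gives a noiseless signal.
#' @param sample_rate_hz Audio sampling rate \eqn{f_s} in Hz.
#' @param carrier_freq_hz Ultrasound transmit (carrier) frequency \eqn{f_0}
#'   in Hz. Default 2 MHz, typical for fetal Doppler probes.
#' @param sound_speed_mps Speed of sound in tissue \eqn{c} in m/s
#'   (default 1540).
#' @param beam_angle_rad Angle \eqn{\theta} between the ultrasound beam and
#'   the direction of motion, in radians, within \eqn{[0, \pi/2]}.
#' @param peak_velocity_mps Peak tissue velocity of the beating heart wall,
#'   m/s.
#' @param seed Optional integer seed; the same configuration and seed always
#'   reproduce the same signal.
#'
#' @return An object of class `doppler_config` (a named list).
#' @seealso [synthesize_doppler()], [cardiac_velocity_waveform()]
#' @export
#' @examples
#' cfg <- doppler_config(heart_rate_bpm = 140, duration_s = 4, snr_db = 10,
#'                       seed = 1)
#' cfg
doppler_config <- function(heart_rate_bpm = 140,
                           duration_s = 8,
                           snr_db = Inf,
                           sample_rate_hz = 4000,
                           carrier_freq_hz = 2e6,
                           sound_speed_mps = 1540,
                           beam_angle_rad = 0,
                           peak_velocity_mps = 0.3,
                           seed = NULL) {
  check_number(heart_rate_bpm, "heart_rate_bpm", min = 30, max = 300)
  check_number(duration_s, "duration_s", min = 0, strict_min = TRUE)
  check_number(sample_rate_hz, "sample_rate_hz", min = 0, strict_min = TRUE)
  check_number(carrier_freq_hz, "carrier_freq_hz", min = 0, strict_min = TRUE)
  check_number(sound_speed_mps, "sound_speed_mps", min = 0, strict_min = TRUE)
  check_number(beam_angle_rad, "beam_angle_rad", min = 0, max = pi / 2)
  check_number(peak_velocity_mps, "peak_velocity_mps", min = 0)
  if (!is.numeric(snr_db) || length(snr_db) != 1L || is.na(snr_db)) {
    stop_invalid("`snr_db` must be a single number (may be Inf).")
  }
  if (!is.null(seed)) check_number(seed, "seed")

  structure(
    list(
      heart_rate_bpm = heart_rate_bpm,
      duration_s = duration_s,
      snr_db = snr_db,
      sample_rate_hz = sample_rate_hz,
      carrier_freq_hz = carrier_freq_hz,
      sound_speed_mps = sound_speed_mps,
      beam_angle_rad = beam_angle_rad,
      peak_velocity_mps = peak_velocity_mps,
      seed = seed
    ),
    class = "doppler_config"
  )
}

#' @export
print.doppler_config <- function(x, ...) {
  cat("<doppler_config>\n")
  cat(sprintf("  heart rate   : %g bpm\n", x$heart_rate_bpm))
  cat(sprintf("  duration     : %g s @ %g Hz\n", x$duration_s,
              x$sample_rate_hz))
  cat(sprintf("  SNR          : %g dB\n", x$snr_db))
  cat(sprintf("  carrier      : %g MHz, c = %g m/s, angle = %g rad\n",
              x$carrier_freq_hz / 1e6, x$sound_speed_mps, x$beam_angle_rad))
  cat(sprintf("  peak velocity: %g m/s\n", x$peak_velocity_mps))
  if (!is.null(x$seed)) cat(sprintf("  seed         : %d\n", as.integer(x$seed)))
  invisible(x)
}

#' Construct a Doppler signal object
#'
#' A `doppler_signal` is a tibble with columns `time_s` and `amplitude`, a
#' `sample_rate_hz` attribute, and an optional `truth_bpm` attribute holding
#' the ground-truth heart rate when the signal was synthesized.
#'
#' @param samples Numeric vector of signal samples (arbitrary amplitude
#'   units); all values must be finite.
#' @param sample_rate_hz Sampling rate in Hz.
#' @param truth_bpm Optional ground-truth heart rate in bpm.
#'
#' @return A tibble of class `doppler_signal`.
#' @export
doppler_signal <- function(samples, sample_rate_hz, truth_bpm = NULL) {
  if (!is.numeric(samples) || anyNA(samples) || !all(is.finite(samples))) {
    stop_invalid("`samples` must be a finite numeric vector.")
  }
  check_number(sample_rate_hz, "sample_rate_hz", min = 0, strict_min = TRUE)
  out <- tibble(
    time_s = (seq_along(samples) - 1) / sample_rate_hz,
    amplitude = as.numeric(samples)
  )
  class(out) <- c("doppler_signal", class(out))
  attr(out, "sample_rate_hz") <- sample_rate_hz
  attr(out, "truth_bpm") <- truth_bpm
  out
}

#' Sampling rate of a signal or envelope object
#'
#' @param x A `doppler_signal` or `doppler_envelope`.
#' @return Sampling rate in Hz.
#' @export
sample_rate <- function(x) {
  r <- attr(x, "sample_rate_hz")
  if (is.null(r)) stop_invalid("Object carries no `sample_rate_hz` attribute.")
  r
}

# Run code under a temporary RNG state seeded with `seed`; the caller's
# global RNG stream is left untouched.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}
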