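#' Doppler frequency shift of a moving reflector
#'
#' Reflected-wave (two-way) Doppler relation: an ultrasound beam of carrier
#' frequency \eqn{f_0} hitting an interface moving at velocity \eqn{v} at
#' angle \eqn{\theta} to the beam returns an echo offset by
#' \deqn{f_D = \frac{2 v f_0 \cos\theta}{c},}
#' where \eqn{c} is the speed of sound in tissue. The sign of the shift
#' follows the sign of the velocity.
#'
#' @param velocity_mps Reflector velocity in m/s (vectorised; signed).
#' @param carrier_freq_hz Carrier frequency \eqn{f_0} in Hz.
#' @param beam_angle_rad Beam-to-motion angle \eqn{\theta} in radians.
#' @param sound_speed_mps Speed of sound \eqn{c} in m/s; must be positive.
#'
#' @return Frequency shift in Hz, same length as `velocity_mps`.
#' @export
#' @examples
#' doppler_shift(0.1, 2e6, 0, 1540)  # about 260 Hz
doppler_shift <- function(velocity_mps, carrier_freq_hz, beam_angle_rad,
                          sound_speed_mps) {
  if (!is.numeric(sound_speed_mps) || length(sound_speed_mps) != 1L ||
      !is.finite(sound_speed_mps) || sound_speed_mps <= 0) {
    stop_invalid("`sound_speed_mps` must be a single positive number.")
  }
  check_number(carrier_freq_hz, "carrier_freq_hz", min = 0, strict_min = TRUE)
  check_number(beam_angle_rad, "beam_angle_rad")
  2 * velocity_mps * carrier_freq_hz * cos(beam_angle_rad) / sound_speed_mps
}

# Velocity trace as a bare numeric vector; one raised-cosine systolic pulse
# (width 30% of the cycle) per beat.
velocity_trace <- function(config, pulse_frac = 0.3) {
  n <- round(config$duration_s * config$sample_rate_hz)
  t <- (seq_len(n) - 1) / config$sample_rate_hz
  period <- 60 / config$heart_rate_bpm
  phase <- t %% period
  w <- pulse_frac * period
  v <- ifelse(phase < w,
              0.5 * (1 - cos(2 * pi * phase / w)),
              0)
  config$peak_velocity_mps * v
}

#' Parametric cardiac velocity waveform
#'
#' Generates the tissue-velocity trace the simulator drives the Doppler
#' shift with: one raised-cosine systolic pulse per beat, pulse width 30%
#' of the cardiac cycle, zero velocity in diastole. The trace is periodic
#' with fundamental period `60 / heart_rate_bpm` seconds and peak magnitude
#' `peak_velocity_mps`.
#'
#' @param config A [doppler_config()].
#'
#' @return A tibble with columns `time_s` and `velocity_mps`, carrying a
#'   `sample_rate_hz` attribute.
#' @export
#' @examples
#' cfg <- doppler_config(heart_rate_bpm = 120, duration_s = 2)
#' vw <- cardiac_velocity_waveform(cfg)
#' sum(diff(sign(diff(vw$velocity_mps))) < 0)  # local maxima: one per beat
cardiac_velocity_waveform <- function(config) {
  stopifnot(inherits(config, "doppler_config"))
  v <- velocity_trace(config)
  out <- tibble(
    time_s = (seq_along(v) - 1) / config$sample_rate_hz,
    velocity_mps = v
  )
  attr(out, "sample_rate_hz") <- config$sample_rate_hz
  out
}

#' Synthesize an ultrasound Doppler audio signal
#'
#' Produces a single-channel Doppler audio signal with known ground-truth
#' heart rate. The instantaneous frequency of the tone is the per-sample
#' Doppler shift of the cardiac velocity waveform; the amplitude is
#' modulated by the (normalised) velocity magnitude, so the beat envelope is
#' recoverable by rectification and low-pass filtering. White Gaussian noise
#' is added at the configured SNR (measured against the clean signal power).
#'
#' @param config A [doppler_config()]. `config$seed` makes the output
#'   reproducible; the caller's RNG state is not disturbed.
#'
#' @return A [doppler_signal()] with `truth_bpm` set to
#'   `config$heart_rate_bpm`.
#' @export
#' @examples
#' sig <- synthesize_doppler(doppler_config(heart_rate_bpm = 140,
#'                                          duration_s = 2, seed = 1))
#' attr(sig, "truth_bpm")
synthesize_doppler <- function(config) {
  stopifnot(inherits(config, "doppler_config"))
  peak_shift <- doppler_shift(config$peak_velocity_mps,
                              config$carrier_freq_hz,
                              config$beam_angle_rad,
                              config$sound_speed_mps)
  if (config$sample_rate_hz < 2 * abs(peak_shift)) {
    abort(sprintf(
      "Sampling rate %g Hz is below twice the peak Doppler shift (%g Hz); the tone would alias.",
      config$sample_rate_hz, abs(peak_shift)),
      class = "fhrdoppler_aliasing_error")
  }

  v <- velocity_trace(config)
  f_inst <- doppler_shift(v, config$carrier_freq_hz, config$beam_angle_rad,
                          config$sound_speed_mps)
  phase <- 2 * pi * cumsum(f_inst) / config$sample_rate_hz
  amp <- if (config$peak_velocity_mps > 0) v / config$peak_velocity_mps else v
  clean <- amp * sin(phase)

  samples <- with_seed(config$seed, {
    if (is.infinite(config$snr_db)) {
      clean
    } else {
      p_clean <- mean(clean^2)
      p_noise <- p_clean / 10^(config$snr_db / 10)
      clean + rnorm(length(clean), sd = sqrt(p_noise))
    }
  })

  doppler_signal(samples, config$sample_rate_hz,
                 truth_bpm = config$heart_rate_bpm)
}
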