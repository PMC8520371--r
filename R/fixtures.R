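#' Simulate an umbilical-artery velocity trace for a target sFGR type
#'
#' Builds a signed velocity trace (cm/s) whose per-cycle end-diastolic
#' velocity pattern matches one of the sFGR Doppler classes: all cycles
#' end-diastolic positive (`"I"`), all absent/reversed (`"II"`), or
#' alternating (`"III"`). Each cycle is a raised-cosine systolic pulse on
#' top of a plateau that decays to the cycle's target EDV in diastole.
#'
#' @param type `"I"`, `"II"` or `"III"`.
#' @param heart_rate_bpm Heart rate used for cycle length.
#' @param n_cycles Number of cardiac cycles.
#' @param sample_rate_hz Trace sampling rate (Hz).
#' @param peak_cmps Systolic peak velocity (cm/s).
#' @param edv_normal_cmps,edv_abnormal_cmps EDV targets for normal and
#'   absent/reversed cycles (cm/s).
#'
#' @return A tibble with `time_s` and `velocity_cmps`, carrying a
#'   `sample_rate_hz` attribute.
#' @export
#' @examples
#' tr <- simulate_ua_trace("III", n_cycles = 6)
#' classify_sfgr_type(end_diastolic_velocities(tr, 100, 140))
simulate_ua_trace <- function(type = c("I", "II", "III"),
                              heart_rate_bpm = 140,
                              n_cycles = 8,
                              sample_rate_hz = 100,
                              peak_cmps = 40,
                              edv_normal_cmps = 6,
                              edv_abnormal_cmps = -3) {
  type <- match.arg(type)
  check_number(n_cycles, "n_cycles", min = 3)
  cycle_len <- round(60 / heart_rate_bpm * sample_rate_hz)
  edv <- switch(type,
    I = rep(edv_normal_cmps, n_cycles),
    II = rep(edv_abnormal_cmps, n_cycles),
    III = rep(c(edv_normal_cmps, edv_abnormal_cmps), length.out = n_cycles)
  )
  phase <- (seq_len(cycle_len) - 1) / cycle_len
  pulse <- ifelse(phase < 0.3, 0.5 * (1 - cos(2 * pi * phase / 0.3)), 0)
  decay <- pmin(1, phase / 0.6)  # plateau-to-EDV ramp, flat by end-diastole
  v <- unlist(lapply(edv, function(e) {
    base <- peak_cmps * 0.25 + (e - peak_cmps * 0.25) * decay
    base + (peak_cmps - max(base)) * pulse
  }), use.names = FALSE)
  out <- tibble(
    time_s = (seq_along(v) - 1) / sample_rate_hz,
    velocity_cmps = v
  )
  attr(out, "sample_rate_hz") <- sample_rate_hz
  out
}

#' Generate the standard fixture battery
#'
#' Writes a reproducible test battery to `out_dir`: synthetic Doppler WAV
#' signals at heart rates 60/120/140/160/240 bpm, noiseless and at SNR
#' 0/10/20 dB; umbilical-artery trace CSVs for sFGR Types I-III; CSVs of
#' the example cohort summary tables ([twin_cohort_tables()]); and a
#' `manifest.csv` listing the ground truth for every file. The same seed
#' always reproduces byte-identical files.
#'
#' @param out_dir Output directory (created if missing; must be writable).
#' @param seed Integer seed driving all signal noise.
#' @param duration_s Length of each Doppler signal (default 8 s).
#'
#' @return The manifest as a tibble (invisibly written to
#'   `out_dir/manifest.csv`).
#' @export
generate_fixtures <- function(out_dir, seed = 1, duration_s = 8) {
  ok <- dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir) || file.access(out_dir, 2) != 0) {
    abort(sprintf("Cannot write to directory: %s", out_dir),
          class = "fhrdoppler_io_error")
  }
  hrs <- c(60, 120, 140, 160, 240)
  snrs <- c(Inf, 0, 10, 20)
  rows <- list()
  k <- 0L
  for (hr in hrs) {
    for (snr in snrs) {
      k <- k + 1L
      label <- if (is.infinite(snr)) "clean" else sprintf("snr%02d", snr)
      fname <- sprintf("doppler_hr%03d_%s.wav", hr, label)
      cfg <- doppler_config(heart_rate_bpm = hr, duration_s = duration_s,
                            snr_db = snr, seed = seed * 1000 + k)
      write_signal(synthesize_doppler(cfg), file.path(out_dir, fname))
      rows[[length(rows) + 1L]] <- tibble(
        file = fname, kind = "doppler_signal", heart_rate_bpm = hr,
        snr_db = snr, sfgr_type = NA_character_
      )
    }
  }
  for (ty in c("I", "II", "III")) {
    fname <- sprintf("ua_trace_type_%s.csv", ty)
    tr <- simulate_ua_trace(ty, heart_rate_bpm = 140, n_cycles = 8)
    utils::write.csv(tr, file.path(out_dir, fname), row.names = FALSE)
    rows[[length(rows) + 1L]] <- tibble(
      file = fname, kind = "ua_trace", heart_rate_bpm = 140,
      snr_db = Inf, sfgr_type = ty
    )
  }
  tabs <- twin_cohort_tables()
  for (nm in names(tabs)) {
    fname <- paste0("cohort_", nm, ".csv")
    utils::write.csv(tabs[[nm]], file.path(out_dir, fname), row.names = FALSE)
    rows[[length(rows) + 1L]] <- tibble(
      file = fname, kind = "summary_table", heart_rate_bpm = NA_real_,
      snr_db = NA_real_, sfgr_type = NA_character_
    )
  }
  manifest <- dplyr::bind_rows(rows)
  manifest$seed <- seed
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(manifest)
}
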