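#' Per-cycle end-diastolic velocities of an umbilical-artery trace
#'
#' Segments a velocity trace into cardiac cycles of length
#' `60 / heart_rate_bpm` seconds and extracts, for each complete cycle, the
#' minimum velocity over the final 20% of the cycle — the end-diastolic
#' velocity (EDV). Absent or reversed end-diastolic flow shows up as EDV at
#' or below zero.
#'
#' @param trace A data frame with a `velocity_cmps` column (signed
#'   umbilical-artery velocity, cm/s), or a bare numeric vector.
#' @param sample_rate_hz Sampling rate of the trace in Hz.
#' @param heart_rate_bpm Fetal heart rate used for cycle segmentation.
#'
#' @return A tibble of class `ua_cycles` with columns `cycle` and
#'   `edv_cmps`; at least 3 complete cycles are required.
#' @export
#' @examples
#' t <- seq(0, 3, by = 1 / 100)
#' v <- 30 + 25 * sin(2 * pi * 2 * t)   # 120 bpm, EDV about 5 cm/s
#' end_diastolic_velocities(v, 100, 120)
end_diastolic_velocities <- function(trace, sample_rate_hz, heart_rate_bpm) {
  v <- if (is.data.frame(trace)) trace$velocity_cmps else trace
  if (is.null(v) || !is.numeric(v) || !all(is.finite(v))) {
    stop_invalid("`trace` must supply finite velocities (column `velocity_cmps`).")
  }
  check_number(sample_rate_hz, "sample_rate_hz", min = 0, strict_min = TRUE)
  check_number(heart_rate_bpm, "heart_rate_bpm", min = 0, strict_min = TRUE)

  cycle_len <- round(60 / heart_rate_bpm * sample_rate_hz)
  n_cycles <- length(v) %/% cycle_len
  if (n_cycles < 3) {
    stop_insufficient(sprintf(
      "Trace covers %d complete cycles; at least 3 are needed.", n_cycles))
  }
  tail_start <- ceiling(0.8 * cycle_len) + 1L
  edv <- vapply(seq_len(n_cycles), function(k) {
    cyc <- v[((k - 1L) * cycle_len + 1L):(k * cycle_len)]
    min(cyc[tail_start:cycle_len])
  }, numeric(1))
  out <- tibble(cycle = seq_len(n_cycles), edv_cmps = edv)
  class(out) <- c("ua_cycles", class(out))
  out
}

#' Classify an umbilical-artery waveform into sFGR Doppler types
#'
#' Selective fetal growth restriction (sFGR) in monochorionic twins is
#' subtyped by the umbilical-artery end-diastolic flow pattern:
#' * **Type I** — normal (positive) diastolic flow in every cycle;
#' * **Type II** — continuously absent or reversed end-diastolic flow
#'   (every cycle abnormal);
#' * **Type III** — intermittently absent or reversed end-diastolic flow
#'   (a mixture of normal and abnormal cycles).
#'
#' "Absent" flow is operationalised as EDV at or below a small dead-band
#' `edv_epsilon` (cm/s), since measured velocities are never exactly zero.
#'
#' @param cycles A `ua_cycles` tibble from [end_diastolic_velocities()], or
#'   any data frame with an `edv_cmps` column (at least 3 cycles).
#' @param edv_epsilon Dead-band below which end-diastolic flow counts as
#'   absent, in cm/s (default 0.5).
#'
#' @return A one-row tibble with `type` (`"I"`, `"II"` or `"III"`),
#'   `fraction_abnormal`, and `n_cycles`.
#' @export
#' @examples
#' classify_sfgr_type(tibble::tibble(edv_cmps = c(5, 0, 4, -1)))  # Type III
classify_sfgr_type <- function(cycles, edv_epsilon = 0.5) {
  edv <- if (is.data.frame(cycles)) cycles$edv_cmps else cycles
  if (is.null(edv) || !is.numeric(edv) || !all(is.finite(edv))) {
    stop_invalid("`cycles` must supply finite EDV values (column `edv_cmps`).")
  }
  if (length(edv) < 3) {
    stop_insufficient("At least 3 cardiac cycles are needed to call a type.")
  }
  check_number(edv_epsilon, "edv_epsilon", min = 0)
  abnormal <- edv <= edv_epsilon
  frac <- mean(abnormal)
  type <- if (all(abnormal)) "II" else if (!any(abnormal)) "I" else "III"
  tibble(type = type, fraction_abnormal = frac, n_cycles = length(edv))
}

#' Small-for-gestational-age screening against a 10th-percentile reference
#'
#' Flags a fetus as small for gestational age (SGA) when the ultrasound
#' estimated fetal weight falls strictly below the 10th percentile for the
#' gestational week. The reference 10th-percentile weights are supplied as
#' a table and linearly interpolated between tabulated weeks. The
#' monochorionic-twin sFGR definition applies this rule to the smaller
#' twin.
#'
#' @param estimated_weight_g Estimated fetal weight in grams (vectorised).
#' @param gestational_week Gestational age in weeks; must lie within the
#'   reference table's range.
#' @param reference A data frame with columns `week` and `p10_weight_g`
#'   (strictly increasing in `week`); defaults to the packaged synthetic
#'   demonstration table (see [growth_reference_demo()]).
#'
#' @return Logical: `TRUE` when the weight is below the 10th percentile.
#' @export
#' @examples
#' is_sga(1444, 32)
#' is_sga(2400, 32)
is_sga <- function(estimated_weight_g, gestational_week,
                   reference = growth_reference_demo()) {
  if (!is.numeric(estimated_weight_g) || anyNA(estimated_weight_g) ||
      any(estimated_weight_g < 0)) {
    stop_invalid("`estimated_weight_g` must be non-negative.")
  }
  check_number(gestational_week, "gestational_week")
  if (!all(c("week", "p10_weight_g") %in% names(reference))) {
    stop_invalid("`reference` needs columns `week` and `p10_weight_g`.")
  }
  wk <- reference$week
  if (gestational_week < min(wk) || gestational_week > max(wk)) {
    abort(sprintf(
      "Gestational week %g is outside the reference range %g-%g.",
      gestational_week, min(wk), max(wk)),
      class = "fhrdoppler_out_of_range")
  }
  p10 <- approx(wk, reference$p10_weight_g, xout = gestational_week)$y
  estimated_weight_g < p10
}

#' Synthetic demonstration growth reference
#'
#' A smooth, strictly increasing 10th-percentile estimated-fetal-weight
#' table (weeks 24--40) shipped for demonstrations and tests. It is a
#' synthetic table, not a published growth standard: for clinical use,
#' supply your population's reference via the `reference` argument of
#' [is_sga()].
#'
#' @return A tibble with columns `week` and `p10_weight_g`.
#' @export
growth_reference_demo <- function() {
  path <- system.file("extdata", "growth_p10_demo.csv",
                      package = "fhrdoppler", mustWork = TRUE)
  as_tibble(utils::read.csv(path))
}
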