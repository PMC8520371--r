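# ggplot2 autoplot methods for the package's result types.

#' Plot a Doppler signal
#'
#' @param object A [doppler_signal()].
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.doppler_signal <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$time_s, y = .data$amplitude)) +
    ggplot2::geom_line(linewidth = 0.2, colour = "grey30") +
    ggplot2::labs(x = "Time (s)", y = "Amplitude",
                  title = "Doppler audio signal") +
    ggplot2::theme_minimal()
}

#' Plot a demodulated beat envelope
#'
#' @param object A `doppler_envelope` from [demodulate()].
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.doppler_envelope <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$time_s, y = .data$value)) +
    ggplot2::geom_line(colour = "firebrick") +
    ggplot2::labs(x = "Time (s)", y = "Envelope",
                  title = "Demodulated beat envelope") +
    ggplot2::theme_minimal()
}

#' Plot a fetal heart rate track
#'
#' Window-by-window heart rate estimates against the 120--160 bpm normal
#' band; points are coloured by status and the dashed line marks the
#' ground-truth rate when the signal was synthetic.
#'
#' @param object An `fhr_track` from [track()].
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.fhr_track <- function(object, ...) {
  e <- tidy(object)
  p <- ggplot2::ggplot(e, ggplot2::aes(x = .data$window_start_s,
                                       y = .data$bpm)) +
    ggplot2::annotate("rect", xmin = -Inf, xmax = Inf, ymin = 120,
                      ymax = 160, alpha = 0.15, fill = "seagreen") +
    ggplot2::geom_line(na.rm = TRUE, colour = "grey40") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$status), na.rm = TRUE) +
    ggplot2::labs(x = "Window start (s)", y = "FHR (bpm)",
                  colour = "Status",
                  title = "Fetal heart rate track",
                  subtitle = "Shaded band: normal 120-160 bpm") +
    ggplot2::theme_minimal()
  if (!is.null(object$truth_bpm)) {
    p <- p + ggplot2::geom_hline(yintercept = object$truth_bpm,
                                 linetype = "dashed", colour = "grey20")
  }
  p
}

#' Plot per-cycle end-diastolic velocities
#'
#' @param object A `ua_cycles` tibble from [end_diastolic_velocities()].
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.ua_cycles <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$cycle, y = .data$edv_cmps)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey50") +
    ggplot2::geom_col(ggplot2::aes(fill = .data$edv_cmps > 0), width = 0.6,
                      show.legend = FALSE) +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "steelblue",
                                          `FALSE` = "firebrick")) +
    ggplot2::labs(x = "Cardiac cycle", y = "End-diastolic velocity (cm/s)",
                  title = "Umbilical-artery end-diastolic velocities") +
    ggplot2::theme_minimal()
}
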