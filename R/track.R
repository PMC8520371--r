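#' Track fetal heart rate through a Doppler signal
#'
#' End-to-end detector: demodulates the Doppler signal once, slides a
#' window over the beat envelope, estimates one heart rate per window by
#' the lookup-table autocorrelation search (or the AMDF alternative), and
#' smooths the resulting rate series with a 3-point running median.
#' Windows reported as `no_signal` are excluded from the smoothing.
#'
#' @param signal A [doppler_signal()].
#' @param window_s Analysis window length in seconds (default 4; at the
#'   50 bpm search floor this still holds more than three beat periods).
#' @param hop_s Hop between successive windows in seconds (default 1).
#' @param method `"autocorr"` (default) or `"amdf"`.
#' @param hr_min_bpm,hr_max_bpm,step_bpm Heart-rate search grid passed to
#'   [build_lookup()].
#' @param min_confidence Minimum per-window confidence (see
#'   [estimate_hr()]).
#' @param cutoff_hz,envelope_rate_hz Demodulation parameters (see
#'   [demodulate()]).
#'
#' @return An object of class `fhr_track`: use [tidy()] for the per-window
#'   estimates (`window_start_s`, `bpm`, `bpm_raw`, `confidence`,
#'   `status`), [glance()] for a one-row summary, and [autoplot()] to plot
#'   the trace against the 120--160 bpm normal band.
#' @export
#' @examples
#' sig <- synthesize_doppler(doppler_config(heart_rate_bpm = 150,
#'                                          duration_s = 8, seed = 2))
#' trk <- track(sig)
#' tidy(trk)
track <- function(signal,
                  window_s = 4,
                  hop_s = 1,
                  method = c("autocorr", "amdf"),
                  hr_min_bpm = 50,
                  hr_max_bpm = 240,
                  step_bpm = 1,
                  min_confidence = 0.3,
                  cutoff_hz = 10,
                  envelope_rate_hz = 500) {
  method <- match.arg(method)
  check_number(window_s, "window_s", min = 0, strict_min = TRUE)
  check_number(hop_s, "hop_s", min = 0, strict_min = TRUE)

  env <- demodulate(signal, cutoff_hz = cutoff_hz,
                    decimate_to_hz = envelope_rate_hz)
  fs <- sample_rate(env)
  wlen <- round(window_s * fs)
  hop <- max(1L, round(hop_s * fs))
  n <- nrow(env)
  if (n < wlen) {
    stop_insufficient(sprintf(
      "Signal provides %d envelope samples but one %g s window needs %d.",
      n, window_s, wlen))
  }
  table <- build_lookup(fs, hr_min_bpm, hr_max_bpm, step_bpm)
  if (max(table$serial_number) >= wlen) {
    stop_invalid(
      "Window is shorter than the longest candidate beat period; widen `window_s` or raise `hr_min_bpm`.")
  }

  starts <- seq(1L, n - wlen + 1L, by = hop)
  est <- purrr::map_dfr(starts, function(s) {
    win <- env[s:(s + wlen - 1L), ]
    if (method == "autocorr") {
      ac <- autocorrelate(win, max_lag = max(table$serial_number))
      estimate_hr(ac, table, min_confidence)
    } else {
      estimate_hr_amdf(win, table, min_confidence)
    }
  })

  bpm_raw <- est$bpm
  bpm <- bpm_raw
  valid <- !is.na(bpm_raw)
  if (sum(valid) >= 3) {
    bpm[valid] <- as.numeric(stats::runmed(bpm_raw[valid], k = 3,
                                           endrule = "median"))
  }
  status <- est$status
  status[valid] <- classify_fhr(bpm[valid])

  estimates <- tibble(
    window_start_s = (starts - 1L) / fs,
    bpm = bpm,
    bpm_raw = bpm_raw,
    confidence = est$confidence,
    status = status
  )

  structure(
    list(
      estimates = estimates,
      method = method,
      window_s = window_s,
      hop_s = hop_s,
      min_confidence = min_confidence,
      hr_range_bpm = c(hr_min_bpm, hr_max_bpm),
      envelope_rate_hz = fs,
      truth_bpm = attr(signal, "truth_bpm")
    ),
    class = "fhr_track"
  )
}

#' @export
print.fhr_track <- function(x, ...) {
  g <- glance(x)
  cat(sprintf("<fhr_track> %d windows (%s, %g s window / %g s hop)\n",
              g$n_windows, x$method, x$window_s, x$hop_s))
  cat(sprintf("  median FHR %s bpm, %d%% windows normal, %d no-signal\n",
              format(g$median_bpm), round(100 * g$prop_normal),
              g$n_no_signal))
  if (!is.null(x$truth_bpm)) {
    cat(sprintf("  ground truth: %g bpm\n", x$truth_bpm))
  }
  invisible(x)
}

#' @rdname track
#' @param x An `fhr_track`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.fhr_track <- function(x, ...) {
  x$estimates
}

#' @rdname track
#' @exportS3Method generics::glance
glance.fhr_track <- function(x, ...) {
  e <- x$estimates
  ok <- !is.na(e$bpm)
  tibble(
    n_windows = nrow(e),
    n_no_signal = sum(e$status == "no_signal"),
    median_bpm = if (any(ok)) median(e$bpm[ok]) else NA_real_,
    prop_normal = if (any(ok)) mean(e$status[ok] == "normal") else NA_real_,
    mean_confidence = mean(e$confidence),
    method = x$method
  )
}
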