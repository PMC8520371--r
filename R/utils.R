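# Shared small helpers.

# Round half away from zero (printed clinical tables round 71.875 -> 71.9,
# unlike round()'s round-half-to-even).
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

check_number <- function(x, name, min = -Inf, max = Inf, strict_min = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name),
          class = "fhrdoppler_invalid_parameter")
  }
  lo_ok <- if (strict_min) x > min else x >= min
  if (!lo_ok || x > max) {
    abort(sprintf("`%s` = %g is outside the allowed range.", name, x),
          class = "fhrdoppler_invalid_parameter")
  }
  invisible(x)
}

stop_invalid <- function(msg) {
  abort(msg, class = "fhrdoppler_invalid_parameter")
}

stop_insufficient <- function(msg) {
  abort(msg, class = "fhrdoppler_insufficient_data")
}

stop_format <- function(msg) {
  abort(msg, class = "fhrdoppler_format_error")
}
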