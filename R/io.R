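# Signal file I/O: mono 16-bit PCM WAV and a self-describing flat CSV
# dialect (comment line `# sample_rate_hz=<f>`, then one sample per line).
# No WAV-handling R package is declared upstream, so the minimal RIFF
# reader/writer lives here.

#' Read a Doppler signal from WAV or CSV
#'
#' WAV files must be single-channel (mono) 16-bit PCM; samples are scaled
#' to `[-1, 1]`. CSV files use the package's flat dialect: a comment line
#' `# sample_rate_hz=<f>` followed by one sample per line; a CSV without
#' that header is only accepted when `sample_rate_hz` is given explicitly.
#'
#' @param path Path to the signal file.
#' @param format_hint `"auto"` (by extension, falling back to content
#'   sniffing), `"wav"` or `"csv"`.
#' @param sample_rate_hz Sampling rate override, required for headerless
#'   CSV.
#'
#' @return A [doppler_signal()].
#' @export
read_signal <- function(path, format_hint = c("auto", "wav", "csv"),
                        sample_rate_hz = NULL) {
  format_hint <- match.arg(format_hint)
  if (!file.exists(path)) stop_format(sprintf("File not found: %s", path))
  if (file.size(path) == 0) stop_format(sprintf("File is empty: %s", path))
  fmt <- format_hint
  if (fmt == "auto") {
    ext <- tolower(tools::file_ext(path))
    fmt <- if (ext == "wav") "wav"
           else if (ext %in% c("csv", "txt")) "csv"
           else {
             magic <- readBin(path, "raw", n = 4L)
             if (identical(rawToChar(magic), "RIFF")) "wav" else "csv"
           }
  }
  if (fmt == "wav") read_wav_mono(path) else read_signal_csv(path, sample_rate_hz)
}

#' Write a Doppler signal to WAV or CSV
#'
#' @param signal A [doppler_signal()] (or data frame with `amplitude` and a
#'   `sample_rate_hz` attribute).
#' @param path Output path; format chosen by extension (`.wav` or `.csv`)
#'   unless `format` says otherwise. WAV output is 16-bit PCM mono with
#'   amplitudes clipped to `[-1, 1]`.
#' @param format `"auto"`, `"wav"` or `"csv"`.
#'
#' @return `path`, invisibly.
#' @export
write_signal <- function(signal, path, format = c("auto", "wav", "csv")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (tolower(tools::file_ext(path)) == "wav") "wav" else "csv"
  }
  fs <- sample_rate(signal)
  x <- signal$amplitude
  if (format == "wav") {
    write_wav_mono(x, fs, path)
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(sprintf("# sample_rate_hz=%.10g", fs), con)
    writeLines(formatC(x, format = "g", digits = 10), con)
  }
  invisible(path)
}

read_signal_csv <- function(path, sample_rate_hz = NULL) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) stop_format("CSV signal file has no content.")
  header <- grep("^#", lines, value = TRUE)
  rate <- sample_rate_hz
  m <- regmatches(header, regexec("sample_rate_hz\\s*=\\s*([0-9.eE+-]+)", header))
  hit <- which(lengths(m) == 2L)
  if (length(hit)) rate <- as.numeric(m[[hit[1]]][2])
  if (is.null(rate) || !is.finite(rate) || rate <= 0) {
    stop_format("No `# sample_rate_hz=` header and no explicit sampling rate given.")
  }
  body <- lines[!grepl("^#", lines)]
  samples <- suppressWarnings(as.numeric(body))
  if (length(samples) == 0 || anyNA(samples)) {
    stop_format("CSV signal body must be one numeric sample per line.")
  }
  doppler_signal(samples, rate)
}

read_wav_mono <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- rawToChar(readBin(con, "raw", 4L))
  readBin(con, "integer", 1L, size = 4L, endian = "little")  # chunk size
  wave <- rawToChar(readBin(con, "raw", 4L))
  if (!identical(riff, "RIFF") || !identical(wave, "WAVE")) {
    stop_format(sprintf("Not a RIFF/WAVE file: %s", path))
  }
  fmt <- NULL
  samples <- NULL
  repeat {
    id_raw <- readBin(con, "raw", 4L)
    if (length(id_raw) < 4L) break
    id <- rawToChar(id_raw)
    size <- readBin(con, "integer", 1L, size = 4L, endian = "little")
    if (identical(id, "fmt ")) {
      body <- readBin(con, "raw", size)
      fmt <- list(
        audio_format = readBin(body[1:2], "integer", 1L, 2L, signed = FALSE,
                               endian = "little"),
        channels = readBin(body[3:4], "integer", 1L, 2L, signed = FALSE,
                           endian = "little"),
        sample_rate = readBin(body[5:8], "integer", 1L, 4L, endian = "little"),
        bits = readBin(body[15:16], "integer", 1L, 2L, signed = FALSE,
                       endian = "little")
      )
    } else if (identical(id, "data")) {
      if (is.null(fmt)) stop_format("WAV data chunk before fmt chunk.")
      if (fmt$channels != 1L) {
        abort(sprintf("Only mono WAV is supported; file has %d channels.",
                      fmt$channels),
              class = "fhrdoppler_unsupported_channels")
      }
      if (fmt$audio_format != 1L || fmt$bits != 16L) {
        stop_format("Only 16-bit PCM WAV is supported.")
      }
      samples <- readBin(con, "integer", n = size %/% 2L, size = 2L,
                         signed = TRUE, endian = "little")
    } else {
      seek(con, size + size %% 2L, origin = "current")
    }
    if (!is.null(samples)) break
  }
  if (is.null(samples)) stop_format("WAV file has no data chunk.")
  doppler_signal(samples / 32767, fmt$sample_rate)
}

write_wav_mono <- function(x, sample_rate_hz, path) {
  pcm <- as.integer(round(pmax(-1, pmin(1, x)) * 32767))
  data_size <- 2L * length(pcm)
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_size), con, size = 4L, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4L, endian = "little")
  writeBin(1L, con, size = 2L, endian = "little")   # PCM
  writeBin(1L, con, size = 2L, endian = "little")   # mono
  writeBin(as.integer(round(sample_rate_hz)), con, size = 4L, endian = "little")
  writeBin(as.integer(round(sample_rate_hz)) * 2L, con, size = 4L,
           endian = "little")                       # byte rate
  writeBin(2L, con, size = 2L, endian = "little")   # block align
  writeBin(16L, con, size = 2L, endian = "little")  # bits per sample
  writeChar("data", con, eos = NULL)
  writeBin(data_size, con, size = 4L, endian = "little")
  writeBin(pcm, con, size = 2L, endian = "little")
  invisible(path)
}
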