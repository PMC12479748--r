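# ECG-to-audio conversion: amplitude normalization, band-limited resampling
# to a standard audio rate, and 16-bit PCM WAV I/O.
#
# Two normalization modes are provided. The "verbatim" mode divides the
# mean-centered signal by max|x(t)| — the directly stated recipe — but that
# denominator does not bound mean-centered values, so outputs can exceed
# [-1, 1]. The default "strict" mode divides by max|x(t) - mu(x)| instead,
# which guarantees the advertised [-1, 1] range. WAV I/O is a minimal RIFF
# 16-bit PCM mono reader/writer (no audio package ships with the toolchain).

#' Construct an audio waveform
#'
#' @param samples numeric vector with |sample| <= 1 (tiny numerical slack).
#' @param sampling_rate Hz.
#' @return An `audio_waveform` object.
#' @export
audio_waveform <- function(samples, sampling_rate) {
  if (length(samples) < 1L) abort_field("samples", "must be non-empty")
  if (max(abs(samples)) > 1 + 1e-9) abort_field("samples", "must lie in [-1, 1]")
  check_number(sampling_rate, "sampling_rate", 1e-9)
  structure(list(samples = as.numeric(samples), sampling_rate = sampling_rate),
            class = "audio_waveform")
}

#' Normalize an ECG trace for audio conversion
#'
#' Verbatim mode: `(x - mean(x)) / max(abs(x))`. Strict mode (default):
#' `(x - mean(x)) / max(abs(x - mean(x)))`, guaranteeing output in \[-1, 1\].
#' A zero denominator (constant trace, or all-zero in verbatim mode) returns
#' an all-zero signal with a warning.
#'
#' @param trace an [ecg_trace()] or numeric vector.
#' @param mode `"strict"` or `"verbatim"`.
#' @return an `ecg_trace` with normalized samples and the input rate.
#' @export
normalize_trace <- function(trace, mode = c("strict", "verbatim")) {
  mode <- match.arg(mode)
  if (is.numeric(trace)) trace <- ecg_trace(trace, 1)
  if (!inherits(trace, "ecg_trace")) abort_field("trace", "must be an ecg_trace")
  x <- trace$samples
  centered <- x - mean(x)
  denom <- if (mode == "strict") max(abs(centered)) else max(abs(x))
  if (denom < .Machine$double.eps) {
    warning("zero-denominator input: returning an all-zero signal")
    y <- numeric(length(x))
  } else {
    y <- centered / denom
  }
  ecg_trace(y, trace$sampling_rate, trace$origin)
}

#' Band-limited resampling to an audio rate
#'
#' Polyphase resampling (via the signal package) with the output length
#' pinned to `round(L * target_rate / source_rate)`.
#'
#' @param trace a normalized [ecg_trace()] (any finite trace is accepted).
#' @param target_rate Hz, default 8000.
#' @return an [audio_waveform()].
#' @export
resample_trace <- function(trace, target_rate = 8000) {
  if (is.numeric(trace)) trace <- ecg_trace(trace, 1)
  check_number(target_rate, "target_rate", 1e-9)
  sr <- trace$sampling_rate
  n_out <- round(length(trace$samples) * target_rate / sr)
  if (abs(sr - target_rate) < 1e-12) {
    y <- trace$samples
  } else {
    g <- gcd_int(round(target_rate * 1000), round(sr * 1000))
    p <- round(target_rate * 1000) / g
    q <- round(sr * 1000) / g
    y <- signal::resample(trace$samples, p, q)
    if (length(y) >= n_out) y <- y[seq_len(n_out)]
    else y <- c(y, rep(y[length(y)], n_out - length(y)))
  }
  # resampling ripple can marginally overshoot; preserve the amplitude bound
  peak <- max(abs(y))
  if (peak > 1) y <- y / peak
  audio_waveform(y, target_rate)
}

gcd_int <- function(a, b) if (b == 0) a else gcd_int(b, a %% b)

#' Write a 16-bit PCM mono WAV file
#'
#' @param w an [audio_waveform()].
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_wav <- function(w, path) {
  if (!inherits(w, "audio_waveform")) abort_field("w", "must be an audio_waveform")
  pcm <- as.integer(pmin(pmax(round(w$samples * 32767), -32768), 32767))
  n <- length(pcm)
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + 2 * n), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")          # fmt chunk size
  writeBin(1L, con, size = 2, endian = "little")           # PCM
  writeBin(1L, con, size = 2, endian = "little")           # mono
  writeBin(as.integer(round(w$sampling_rate)), con, size = 4, endian = "little")
  writeBin(as.integer(round(w$sampling_rate)) * 2L, con, size = 4, endian = "little")
  writeBin(2L, con, size = 2, endian = "little")           # block align
  writeBin(16L, con, size = 2, endian = "little")          # bits per sample
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(2 * n), con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}

#' Read a 16-bit PCM mono WAV file
#'
#' @param path input path.
#' @return an [audio_waveform()].
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4)
  readBin(con, "integer", size = 4, endian = "little")
  wave <- readChar(con, 4)
  if (!identical(riff, "RIFF") || !identical(wave, "WAVE")) {
    stop("not a RIFF/WAVE file: ", path, call. = FALSE)
  }
  rate <- NULL; bits <- NULL; channels <- NULL; fmt <- NULL
  repeat {
    id <- readChar(con, 4)
    if (length(id) == 0 || nchar(id) < 4) stop("no data chunk found", call. = FALSE)
    size <- readBin(con, "integer", size = 4, endian = "little")
    if (id == "fmt ") {
      fmt <- readBin(con, "integer", size = 2, endian = "little")
      channels <- readBin(con, "integer", size = 2, endian = "little")
      rate <- readBin(con, "integer", size = 4, endian = "little")
      readBin(con, "integer", size = 4, endian = "little")
      readBin(con, "integer", size = 2, endian = "little")
      bits <- readBin(con, "integer", size = 2, endian = "little")
      if (size > 16) readBin(con, "raw", n = size - 16)
    } else if (id == "data") {
      if (is.null(fmt)) stop("data chunk before fmt chunk", call. = FALSE)
      if (fmt != 1L || bits != 16L || channels != 1L) {
        stop("unsupported WAV format: expected 16-bit PCM mono", call. = FALSE)
      }
      pcm <- readBin(con, "integer", n = size / 2, size = 2,
                     signed = TRUE, endian = "little")
      return(audio_waveform(pcm / 32767, rate))
    } else {
      readBin(con, "raw", n = size)
    }
  }
}
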