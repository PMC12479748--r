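# Log-Mel spectrogram pipeline: Hann-windowed STFT, triangular Mel
# filterbank on the 2595*log10(1 + f/700) scale, dB conversion referenced to
# the per-spectrogram maximum, and the 224 x 224 x 3 image form consumed by
# the spectrogram classifier.

#' Spectrogram configuration
#'
#' Defaults follow the classifier's preprocessing contract: 22,050 Hz,
#' window 1024, hop 512, 128 Mel bands, Hann window, dB floor -80.
#'
#' @param sampling_rate Hz.
#' @param n_fft FFT/window size in samples.
#' @param hop_length hop in samples (`<= n_fft`).
#' @param n_mels number of Mel bands.
#' @param fmin,fmax filterbank frequency range; `fmax` defaults to Nyquist.
#' @param db_floor clamp for dB values.
#' @param center_padding reflect-pad by `n_fft/2` so frames are centered.
#' @return A `spectrogram_config` object.
#' @export
spectrogram_config <- function(sampling_rate = 22050, n_fft = 1024,
                               hop_length = 512, n_mels = 128, fmin = 0,
                               fmax = sampling_rate / 2, db_floor = -80,
                               center_padding = TRUE) {
  check_number(sampling_rate, "sampling_rate", 1e-9)
  check_number(n_fft, "n_fft", 2)
  check_number(hop_length, "hop_length", 1, n_fft)
  check_number(n_mels, "n_mels", 1)
  check_number(fmin, "fmin", 0)
  if (fmin >= fmax || fmax > sampling_rate / 2 + 1e-9) {
    abort_field("fmax", "must satisfy fmin < fmax <= sampling_rate/2")
  }
  check_flag(center_padding, "center_padding")
  structure(list(sampling_rate = sampling_rate, n_fft = as.integer(n_fft),
                 hop_length = as.integer(hop_length), n_mels = as.integer(n_mels),
                 window = "hann", fmin = fmin, fmax = fmax,
                 db_floor = db_floor, center_padding = center_padding),
            class = "spectrogram_config")
}

#' Short-time Fourier transform
#'
#' Hann-windowed frames every `hop_length` samples; with center padding
#' (reflection by `n_fft/2` on both sides) the frame count is
#' `1 + floor(L / hop_length)`. Returns the one-sided spectrum.
#'
#' @param w an [audio_waveform()] or numeric vector.
#' @param cfg a [spectrogram_config()].
#' @return complex matrix `(n_fft/2 + 1) x n_frames`.
#' @export
stft <- function(w, cfg = spectrogram_config()) {
  x <- if (inherits(w, "audio_waveform")) w$samples else as.numeric(w)
  if (length(x) < 1L) abort_field("w", "must be non-empty")
  nfft <- cfg$n_fft; hop <- cfg$hop_length
  if (cfg$center_padding) {
    pad <- nfft %/% 2
    L <- length(x)
    n_frames <- 1L + floor(L / hop)
    x <- x[reflect_index(seq(1L - pad, L + pad), L)]
  } else {
    if (length(x) < nfft) abort_field("n_fft", "exceeds the signal length")
    n_frames <- 1L + floor((length(x) - nfft) / hop)
  }
  if (length(x) < nfft) abort_field("n_fft", "exceeds the padded signal length")
  win <- hann_window(nfft)
  starts <- (seq_len(n_frames) - 1L) * hop
  frames <- vapply(starts, function(s) {
    idx <- s + seq_len(nfft)
    idx <- pmin(idx, length(x))
    x[idx] * win
  }, numeric(nfft))
  S <- stats::mvfft(frames)
  S[seq_len(nfft %/% 2 + 1L), , drop = FALSE]
}

# Periodic Hann window, the audio-processing convention.
hann_window <- function(n) 0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1) / n)

# Reflection indexing without edge repetition (librosa "reflect" convention);
# valid for arbitrary out-of-range indices.
reflect_index <- function(i, L) {
  if (L == 1) return(rep(1L, length(i)))
  period <- 2L * (L - 1L)
  j <- (i - 1L) %% period
  j <- ifelse(j >= L, period - j, j)
  as.integer(j + 1L)
}

#' Hertz to Mel
#'
#' `M(f) = 2595 * log10(1 + f/700)`.
#' @param f frequency in Hz (>= 0, vectorized).
#' @return Mel value(s).
#' @export
hz_to_mel <- function(f) {
  if (any(f < 0)) abort_field("f", "must be non-negative")
  2595 * log10(1 + f / 700)
}

#' Mel to Hertz (inverse of [hz_to_mel()])
#' @param m Mel value(s).
#' @return frequency in Hz.
#' @export
mel_to_hz <- function(m) 700 * (10^(m / 2595) - 1)

#' Triangular Mel filterbank
#'
#' `n_mels` triangular filters with unit peak, centers equally spaced on the
#' Mel axis between `M(fmin)` and `M(fmax)`.
#'
#' @param cfg a [spectrogram_config()].
#' @return matrix `n_mels x (n_fft/2 + 1)`.
#' @export
mel_filterbank <- function(cfg = spectrogram_config()) {
  n_bins <- cfg$n_fft %/% 2 + 1L
  freqs <- (seq_len(n_bins) - 1) * cfg$sampling_rate / cfg$n_fft
  pts <- mel_to_hz(seq(hz_to_mel(cfg$fmin), hz_to_mel(cfg$fmax),
                       length.out = cfg$n_mels + 2L))
  fb <- matrix(0, cfg$n_mels, n_bins)
  for (i in seq_len(cfg$n_mels)) {
    lo <- pts[i]; ce <- pts[i + 1]; hi <- pts[i + 2]
    up <- (freqs - lo) / (ce - lo)
    down <- (hi - freqs) / (hi - ce)
    fb[i, ] <- pmax(0, pmin(up, down))
  }
  empty <- which(rowSums(fb) == 0)
  if (length(empty)) {
    warning(sprintf("empty Mel filters (FFT resolution too coarse): %s",
                    paste(empty, collapse = ", ")))
  }
  fb
}

#' Compute a Mel spectrogram (power scale)
#'
#' @param w an [audio_waveform()] or numeric vector.
#' @param cfg a [spectrogram_config()].
#' @return A `mel_spectrogram`: list with `values` (`n_mels x n_frames`),
#'   `config`, `is_db = FALSE`.
#' @export
mel_spectrogram <- function(w, cfg = spectrogram_config()) {
  S <- stft(w, cfg)
  power <- Mod(S)^2
  structure(list(values = mel_filterbank(cfg) %*% power, config = cfg,
                 is_db = FALSE),
            class = "mel_spectrogram")
}

#' Convert a power Mel spectrogram to decibels
#'
#' `10 * log10(S / max(S))` clamped below at `db_floor`; the reference is the
#' matrix maximum, so the loudest cell maps to 0 dB.
#'
#' @param m a `mel_spectrogram` on the power scale.
#' @return a `mel_spectrogram` with `is_db = TRUE`.
#' @export
power_to_db <- function(m) {
  if (!inherits(m, "mel_spectrogram")) abort_field("m", "must be a mel_spectrogram")
  if (m$is_db) return(m)
  S <- m$values
  if (any(S < 0)) abort_field("m", "power values must be non-negative")
  ref <- max(S)
  floor_db <- m$config$db_floor
  if (ref <= 0) {
    warning("all-zero spectrogram: every cell set to the dB floor")
    db <- matrix(floor_db, nrow(S), ncol(S))
  } else {
    db <- 10 * log10(pmax(S / ref, 10^(floor_db / 10)))
    db <- pmax(db, floor_db)
  }
  structure(list(values = db, config = m$config, is_db = TRUE),
            class = "mel_spectrogram")
}

#' Convert a dB Mel spectrogram to a 224 x 224 x 3 image
#'
#' Min–max scaled to \[0, 1\], bilinearly resized to 224 x 224, and
#' channel-replicated to three identical channels. A constant spectrogram
#' yields an all-0.5 image with a warning.
#'
#' @param m a dB-scale `mel_spectrogram`.
#' @param size output side length (default 224).
#' @return numeric array `size x size x 3` in \[0, 1\], class
#'   `spectrogram_image`.
#' @export
to_image <- function(m, size = 224L) {
  if (!inherits(m, "mel_spectrogram") || !isTRUE(m$is_db)) {
    abort_field("m", "must be a dB-scale mel_spectrogram")
  }
  v <- m$values
  rng <- range(v)
  if (diff(rng) < .Machine$double.eps) {
    warning("constant spectrogram: returning an all-0.5 image")
    sc <- matrix(0.5, nrow(v), ncol(v))
  } else {
    sc <- (v - rng[1]) / diff(rng)
  }
  res <- EBImage::resize(EBImage::Image(t(sc)), w = size, h = size,
                         filter = "bilinear")
  plane <- t(EBImage::imageData(res))
  plane <- pmin(pmax(plane, 0), 1)
  structure(array(rep(plane, 3), dim = c(size, size, 3)),
            class = "spectrogram_image")
}

#' Full waveform-to-image spectrogram pipeline
#'
#' @inheritParams mel_spectrogram
#' @param size image side length.
#' @return a `spectrogram_image` with attribute `n_frames` (pre-resize frame
#'   count, needed to map time-domain zones into image coordinates).
#' @export
spectrogram_image <- function(w, cfg = spectrogram_config(), size = 224L) {
  m <- power_to_db(mel_spectrogram(w, cfg))
  img <- to_image(m, size)
  attr(img, "n_frames") <- ncol(m$values)
  img
}
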