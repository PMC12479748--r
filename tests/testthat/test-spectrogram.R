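test_that("STFT frame counts and linearity match the contract", {
  cfg <- spectrogram_config()
  S0 <- stft(rep(0, 4096), cfg)
  expect_equal(dim(S0), c(513, 9))
  expect_true(all(Mod(S0) == 0))
  expect_equal(ncol(stft(rep(0.1, 2048), cfg)), 5)   # 1 + floor(2048/512)
  expect_error(stft(rep(0, 100), spectrogram_config(center_padding = FALSE)),
               "n_fft")
})

test_that("a bin-aligned sinusoid peaks at its own bin in interior frames", {
  cfg <- spectrogram_config()
  k <- 40
  t <- (0:22049) / cfg$sampling_rate
  s <- sin(2 * pi * k * cfg$sampling_rate / cfg$n_fft * t)
  S <- Mod(stft(s, cfg))
  interior <- 5:(ncol(S) - 5)
  argmax <- apply(S[, interior], 2, which.max) - 1L
  expect_true(all(argmax == k))
})

test_that("the Mel formula evaluates exactly and monotonically", {
  expect_equal(hz_to_mel(0), 0)
  expect_equal(hz_to_mel(700), 2595 * log10(2))
  expect_error(hz_to_mel(-1), "non-negative")
  set.seed(2)
  f <- sort(runif(50, 0, 11025))
  expect_true(all(diff(hz_to_mel(f)) > 0))
  expect_equal(mel_to_hz(hz_to_mel(f)), f)
})

test_that("triangular filterbank has positive, ordered, unit-peak filters", {
  cfg <- spectrogram_config()
  fb <- mel_filterbank(cfg)
  expect_identical(dim(fb), c(128L, 513L))
  expect_true(all(rowSums(fb) > 0))
  # continuous center frequencies are strictly increasing; the discretized
  # peak bins can only tie where the FFT grid is coarser than the mel spacing
  centers <- mel_to_hz(seq(hz_to_mel(cfg$fmin), hz_to_mel(cfg$fmax),
                           length.out = cfg$n_mels + 2))[2:(cfg$n_mels + 1)]
  expect_true(all(diff(centers) > 0))
  peaks <- apply(fb, 1, which.max)
  expect_true(all(diff(peaks) >= 0))
  expect_true(all(fb >= 0))
  # n_mels = 2: centers at the 1/3 and 2/3 points of the mel axis
  cfg2 <- spectrogram_config(n_mels = 2)
  fb2 <- mel_filterbank(cfg2)
  freqs <- (0:512) * cfg2$sampling_rate / cfg2$n_fft
  centers_hz <- mel_to_hz(hz_to_mel(cfg2$sampling_rate / 2) * c(1, 2) / 3)
  got <- freqs[apply(fb2, 1, which.max)]
  expect_equal(got, centers_hz, tolerance = cfg2$sampling_rate / cfg2$n_fft)
  expect_warning(mel_filterbank(spectrogram_config(n_mels = 4, fmax = 40)),
                 "empty Mel filters")
})

test_that("dB conversion references the matrix maximum and clamps at the floor", {
  cfg <- spectrogram_config()
  m <- structure(list(values = matrix(c(10, 1, 0, 5), 2), config = cfg,
                      is_db = FALSE), class = "mel_spectrogram")
  db <- power_to_db(m)
  expect_equal(max(db$values), 0)
  expect_equal(db$values[2, 1], -10)   # one tenth of the max
  expect_equal(db$values[1, 2], -80)   # zero cell clamps to the floor
  zero <- structure(list(values = matrix(0, 2, 2), config = cfg, is_db = FALSE),
                    class = "mel_spectrogram")
  expect_warning(zdb <- power_to_db(zero), "all-zero")
  expect_true(all(zdb$values == -80))
})

test_that("the image form is 224 x 224 x 3 in [0, 1] with identical channels", {
  w <- audio_waveform(sin(2 * pi * 100 * (0:44099) / 22050) *
                        (0.6 + 0.3 * sin(2 * pi * (0:44099) / 44100)), 22050)
  img <- spectrogram_image(w)
  expect_identical(dim(unclass(img)), c(224L, 224L, 3L))
  expect_gte(min(img), 0); expect_lte(max(img), 1)
  expect_identical(img[, , 1], img[, , 2])
  expect_identical(img[, , 1], img[, , 3])
  m <- power_to_db(mel_spectrogram(w))
  sc <- (m$values - min(m$values)) / diff(range(m$values))
  expect_equal(min(sc), 0); expect_equal(max(sc), 1)
  const <- structure(list(values = matrix(-5, 4, 4),
                          config = spectrogram_config(), is_db = TRUE),
                     class = "mel_spectrogram")
  expect_warning(ci <- to_image(const), "constant")
  expect_true(all(ci == 0.5))
})

test_that("spectrogram power never decreases under amplitude scaling", {
  set.seed(31)
  x <- rnorm(8000) * 0.1
  a <- mel_spectrogram(audio_waveform(x, 22050))$values
  b <- mel_spectrogram(audio_waveform(pmin(pmax(x * 3, -1), 1), 22050))$values
  expect_true(all(b >= a - 1e-12))
})

test_that("the waveform-to-image pipeline is deterministic", {
  w <- audio_waveform(sin(2 * pi * 440 * (0:22049) / 22050), 22050)
  expect_identical(unclass(spectrogram_image(w)), unclass(spectrogram_image(w)))
})
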