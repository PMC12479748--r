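test_that("noise-free generation places beats exactly on the heart-rate grid", {
  rec <- clean_record()
  ann <- rec$annotations
  expect_length(ann$r_peak_indices, 5)
  expect_equal(ann$rr_intervals, rep(1, 4))
  expect_equal(length(rec$trace$samples), 5 * 250)
  # annotation consistency: RR recomputed from indices matches within 1/fs
  expect_equal(diff(ann$r_peak_indices) / 250, ann$rr_intervals,
               tolerance = 1 / 250)
  # every R peak sits inside its QRS window
  for (i in seq_along(ann$r_peak_indices)) {
    expect_gte(ann$r_peak_indices[i], ann$qrs_windows[i, 1])
    expect_lte(ann$r_peak_indices[i], ann$qrs_windows[i, 2])
  }
})

test_that("noise-free beats are identical across the record", {
  rec <- clean_record()
  x <- rec$trace$samples
  half <- 110   # samples on each side of an R peak (within one period)
  windows <- vapply(rec$annotations$r_peak_indices[2:4], function(r) {
    x[(r - half):(r + half)]
  }, numeric(2 * half + 1))
  expect_lt(max(abs(windows - windows[, 1])), 1e-12)
})

test_that("generation is a pure function of its seed", {
  s <- synthetic_ecg_spec(noise_sd = 0.05, seed = 42)
  a <- generate_waveform(s)
  b <- generate_waveform(s)
  expect_identical(a$trace$samples, b$trace$samples)
  s2 <- synthetic_ecg_spec(noise_sd = 0.05, seed = 43)
  expect_false(identical(generate_waveform(s2)$trace$samples, a$trace$samples))
})

test_that("spec validation names the offending field", {
  expect_error(synthetic_ecg_spec(heart_rate = 10), "heart_rate")
  expect_error(synthetic_ecg_spec(sampling_rate = 50), "sampling_rate")
  expect_error(synthetic_ecg_spec(heart_rate = 60, duration = 1.5), "duration")
  expect_error(beat_morphology(amplitude = c(P = 1), width = c(P = 1),
                               center = c(P = 0)), "morphology")
})

test_that("rendering maps amplitude affinely with exact output dimensions", {
  rs <- render_spec(image_height = 128, image_width = 320, grid = FALSE)
  rec <- clean_record()
  img <- render_image(rec$trace, rs)
  expect_identical(dim(unclass(img)), c(128L, 320L))
  # constant trace: single horizontal dark run at the mid-plot row
  flat <- ecg_trace(rep(2.5, 100), 100)
  fimg <- render_image(flat, rs)
  dark_rows <- which(apply(fimg < 128, 1, any))
  expect_lte(diff(range(dark_rows)), rs$trace_thickness)
  expect_equal(mean(dark_rows), 64, tolerance = 2)
})

test_that("datasets have exact per-class counts and are seed-reproducible", {
  ds <- make_ecg_dataset(5, seed = 7, render = FALSE)
  labels <- vapply(ds, `[[`, character(1), "label")
  expect_equal(unname(table(labels)["le_positive"]), 5, ignore_attr = TRUE)
  expect_equal(unname(table(labels)["le_negative"]), 5, ignore_attr = TRUE)
  ds2 <- make_ecg_dataset(5, seed = 7, render = FALSE)
  expect_identical(lapply(ds, function(r) r$trace$samples),
                   lapply(ds2, function(r) r$trace$samples))
})

test_that("classes are separable by ground-truth QRS width", {
  ds <- small_dataset()
  widths <- vapply(ds, function(r) {
    mean(r$annotations$qrs_windows[, 2] - r$annotations$qrs_windows[, 1]) /
      r$trace$sampling_rate
  }, numeric(1))
  labels <- vapply(ds, `[[`, character(1), "label")
  w_pos <- mean(widths[labels == "le_positive"])
  w_neg <- mean(widths[labels == "le_negative"])
  expect_gte(w_pos / w_neg, 1.3)
  # a width-threshold classifier separates the presets
  thr <- (w_pos + w_neg) / 2
  pred <- ifelse(widths > thr, "le_positive", "le_negative")
  expect_gte(mean(pred == labels), 0.9)
})

test_that("dataset files round-trip through the on-disk format", {
  dir <- withr::local_tempdir()
  ds <- make_ecg_dataset(2, seed = 3, render = TRUE,
                         rs = render_spec(image_height = 96, image_width = 200))
  manifest_path <- write_ecg_dataset(ds, dir)
  manifest <- jsonlite::read_json(manifest_path)
  expect_length(manifest, 4)
  tr <- utils::read.csv(manifest[[1]]$trace)
  expect_equal(tr$amplitude, ds[[1]]$trace$samples)
  img <- read_ecg_image(manifest[[1]]$image)
  expect_identical(dim(img)[1:2], c(96L, 200L))
})
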