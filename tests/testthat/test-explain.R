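test_that("the Grad-CAM map composes weights and activations as defined", {
  # single channel, positive gradient: map is the normalized rectified
  # activation itself
  A <- array(0, c(4, 4, 1))
  A[, , 1] <- matrix(c(-1, 0, 2, 4), 4, 4, byrow = TRUE)
  G <- array(0.5, c(4, 4, 1))
  hm <- grad_cam_map(A, G)
  expect_equal(hm, pmax(A[, , 1], 0) / 4)
  # bounded in [0, 1] for arbitrary inputs
  set.seed(6)
  A2 <- array(rnorm(4 * 4 * 3), c(4, 4, 3))
  G2 <- array(rnorm(4 * 4 * 3), c(4, 4, 3))
  hm2 <- grad_cam_map(A2, G2)
  expect_gte(min(hm2), 0); expect_lte(max(hm2), 1)
  # uniformly negative weighted sum of positive activations rectifies to a
  # constant (zero) map -> all zeros with warning
  Apos <- array(abs(A) + 1, dim(A))
  expect_warning(z <- grad_cam_map(Apos, -G), "constant")
  expect_true(all(z == 0))
  expect_error(grad_cam_map(A, G[, 1:2, , drop = FALSE]), "shape")
})

test_that("upsampling to the input grid preserves the [0, 1] range", {
  A <- array(runif(14 * 56), c(14, 56, 1))
  hm <- grad_cam_map(A, array(1, dim(A)), out_shape = c(224, 224))
  expect_identical(dim(hm), c(224L, 224L))
  expect_gte(min(hm), 0); expect_lte(max(hm), 1)
})

test_that("region attention accuracy counts peak-region hits", {
  peaked <- function(r, c) {
    m <- matrix(0, 10, 10); m[r, c] <- 1
    m
  }
  zone <- list(list(label = "QRS", row_min = 1, row_max = 10,
                    col_min = 4, col_max = 6))
  hit <- peaked(5, 5); miss <- peaked(5, 9)
  expect_equal(region_attention_accuracy(list(hit, hit), list(zone, zone)), 100)
  expect_equal(region_attention_accuracy(list(miss, miss), list(zone, zone)), 0)
  expect_equal(region_attention_accuracy(list(hit, miss), list(zone, zone)), 50)
  expect_error(region_attention_accuracy(list(), list()), "empty")
  expect_error(region_attention_accuracy(list(hit), list()), "one annotation")
  # the peak's connected region (not just the peak cell) decides the hit
  spread <- matrix(0, 10, 10)
  spread[5, 7:9] <- c(0.6, 0.8, 1)   # peak at col 9, region reaches col 7... still outside
  expect_equal(region_attention_accuracy(list(spread), list(zone)), 0)
  spread[5, 5:9] <- c(0.6, 0.6, 0.6, 0.8, 1)  # region now reaches the zone
  expect_equal(region_attention_accuracy(list(spread), list(zone)), 100)
})

test_that("QRS overlap is the activated-area fraction inside the zone", {
  hm <- matrix(0, 10, 12)
  hm[3:8, 1:10] <- 1          # 60 activated cells
  mask <- matrix(FALSE, 10, 12)
  mask[3:8, 1:5] <- TRUE      # 30 of them inside
  expect_equal(qrs_overlap(hm, mask), 50)
  expect_equal(qrs_overlap(hm, hm > 0), 100)
  expect_equal(qrs_overlap(hm, !(hm > 0)), 0)
  expect_warning(v <- qrs_overlap(matrix(0.1, 4, 4), matrix(TRUE, 4, 4)),
                 "threshold")
  expect_equal(v, 0)
  expect_error(qrs_overlap(hm, mask[1:5, ]), "shape")
})

test_that("metrics are invariant to positive rescaling of the raw map", {
  set.seed(7)
  A <- array(runif(100), c(10, 10, 1))
  G <- array(1, c(10, 10, 1))
  h1 <- grad_cam_map(A, G)
  h2 <- grad_cam_map(A * 7.3, G)
  expect_equal(h1, h2, tolerance = 1e-12)
})

test_that("mean and sample sd summaries match hand arithmetic", {
  s <- summarize_region_metrics(data.frame(raa = c(80, 100),
                                           qrs_overlap = c(90, 90)))
  expect_equal(nrow(s), 2)
  expect_equal(s$mean[s$metric == "raa"], 90)
  expect_equal(s$sd[s$metric == "raa"], sqrt(200), tolerance = 1e-12)
  expect_equal(s$sd[s$metric == "qrs_overlap"], 0)
  expect_warning(one <- summarize_region_metrics(data.frame(raa = 80)), "sd omitted")
  expect_true(is.na(one$sd))
})

test_that("zone rasterization and the time-to-image mapping stay in bounds", {
  cfg <- spectrogram_config()
  qrs <- matrix(c(100, 160, 2400, 2480), 2, 2, byrow = TRUE)
  zones <- qrs_zones_to_image(qrs, trace_rate = 250, cfg = cfg,
                              n_frames = 431, size = 224)
  expect_length(zones, 2)
  mask <- zones_to_mask(zones, c(224, 224))
  expect_identical(dim(mask), c(224L, 224L))
  expect_true(any(mask))
  for (z in zones) {
    expect_gte(z$col_min, 1); expect_lte(z$col_max, 224)
    expect_lte(z$col_min, z$col_max)
  }
  expect_error(zones_to_mask(list(list(label = "", row_min = 1, row_max = 2,
                                       col_min = 1, col_max = 2)), c(4, 4)),
               "label")
})

test_that("the sign-flip permutation test behaves at its extremes", {
  p_strong <- overlap_permutation_test(rep(80, 20), rep(0.3, 20), seed = 1)
  expect_lt(p_strong$p_value, 0.01)
  set.seed(10)
  null_ov <- 30 + rnorm(20, 0, 2)
  p_null <- overlap_permutation_test(null_ov, rep(0.3, 20), seed = 1)
  expect_gt(p_null$p_value, 0.05)
})
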