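test_that("a residual block with zero weights is the identity map", {
  p <- resnet_block_params(8, seed = 1)
  p$W1[] <- 0; p$W2[] <- 0
  x <- matrix(rnorm(40), 5, 8)
  expect_identical(resnet_block_forward(x, p), x)
  # output shape always equals input shape
  p2 <- resnet_block_params(8, seed = 2)
  expect_identical(dim(resnet_block_forward(x, p2)), dim(x))
  expect_error(resnet_block_forward(matrix(0, 2, 3), p2), "channels")
})

test_that("residual block gradients match finite differences", {
  set.seed(11)
  p <- resnet_block_params(10, seed = 11)
  p$bn1$running_mean <- rnorm(10, 0, 0.3); p$bn1$running_var <- runif(10, 0.5, 1.5)
  p$bn2$running_mean <- rnorm(10, 0, 0.3); p$bn2$running_var <- runif(10, 0.5, 1.5)
  x <- matrix(rnorm(40), 4, 10)
  co <- matrix(rnorm(40), 4, 10)   # random linear functional of the output
  cache <- ecgfusion:::resnet_block_fwd(x, p)
  bw <- ecgfusion:::resnet_block_bwd(co, cache, p)
  ng_x <- numeric_gradient(function(v) sum(ecgfusion:::resnet_block_fwd(matrix(v, 4, 10), p)$out * co),
                           as.vector(x))
  expect_lt(rel_err(ng_x, as.vector(bw$dx)), 1e-5)
  ng_w <- numeric_gradient(function(v) {
    p2 <- p; p2$W1 <- matrix(v, 10, 10)
    sum(ecgfusion:::resnet_block_fwd(x, p2)$out * co)
  }, as.vector(p$W1))
  expect_lt(rel_err(ng_w, as.vector(bw$grads$W1)), 1e-5)
  ng_g <- numeric_gradient(function(v) {
    p2 <- p; p2$bn1$gamma <- v
    sum(ecgfusion:::resnet_block_fwd(x, p2)$out * co)
  }, p$bn1$gamma)
  expect_lt(rel_err(ng_g, bw$grads$bn1$gamma), 1e-5)
})

test_that("the BiRNN obeys its zero-parameter and symmetry identities", {
  p <- birnn_params(3, 4, 2, seed = 21)
  x <- matrix(rnorm(15), 5, 3)
  # all parameters zero -> y_t = b_y everywhere
  z <- p
  for (nm in c("Wf", "Vf", "Wb", "Vb", "U")) z[[nm]][] <- 0
  z$bf[] <- 0; z$bb[] <- 0; z$by <- c(0.7, -0.2)
  out <- birnn_forward(x, z)$out
  expect_true(all(abs(sweep(out, 2, c(0.7, -0.2))) < 1e-12))
  # tying backward params to forward: reversing the input swaps trajectories
  tied <- p; tied$Wb <- p$Wf; tied$Vb <- p$Vf; tied$bb <- p$bf
  fw <- birnn_forward(x, tied)
  rv <- birnn_forward(x[5:1, ], tied)
  expect_equal(rv$h_backward[5:1, ], fw$h_forward, tolerance = 1e-12)
  # T = 1 with tied params: forward and backward states coincide
  one <- birnn_forward(x[1, , drop = FALSE], tied)
  expect_equal(one$h_forward, one$h_backward, tolerance = 1e-12)
})

test_that("BiRNN gradients match finite differences", {
  set.seed(22)
  p <- birnn_params(3, 4, 2, seed = 22)
  x <- matrix(rnorm(15), 5, 3)
  co <- matrix(rnorm(10), 5, 2)
  cache <- ecgfusion:::birnn_fwd(x, p)
  bw <- ecgfusion:::birnn_bwd(co, cache, p)
  for (nm in c("Wf", "Vf", "Wb", "Vb", "U")) {
    ng <- numeric_gradient(function(v) {
      p2 <- p; p2[[nm]] <- matrix(v, nrow(p[[nm]]), ncol(p[[nm]]))
      sum(ecgfusion:::birnn_fwd(x, p2)$out * co)
    }, as.vector(p[[nm]]))
    expect_lt(rel_err(ng, as.vector(bw$grads[[nm]])), 1e-5)
  }
  ng_x <- numeric_gradient(function(v) sum(ecgfusion:::birnn_fwd(matrix(v, 5, 3), p)$out * co),
                           as.vector(x))
  expect_lt(rel_err(ng_x, as.vector(bw$dx)), 1e-5)
})

test_that("spectrogram classifier gradients match finite differences", {
  set.seed(33)
  p <- ecgfusion:::subsystem2_params(2, 33)
  x <- matrix(rnorm(28 * 112), 28, 112)
  dl <- c(1, -1)
  fw <- ecgfusion:::s2_forward(p, x)
  g <- ecgfusion:::s2_backward(p, fw$cache, dl)
  score <- function(params) sum(ecgfusion:::s2_forward(params, x)$logits * dl)
  ng1 <- numeric_gradient(function(v) { p2 <- p; p2$conv1$W <- matrix(v, 9, 8); score(p2) },
                          as.vector(p$conv1$W))
  expect_lt(rel_err(ng1, as.vector(g$conv1$W)), 1e-5)
  ng3 <- numeric_gradient(function(v) { p2 <- p; p2$conv3$W[, 1] <- v; score(p2) },
                          p$conv3$W[, 1])
  expect_lt(rel_err(ng3, g$conv3$W[, 1]), 1e-5)
  ngh <- numeric_gradient(function(v) { p2 <- p; p2$head$W[, 2] <- v; score(p2) },
                          p$head$W[, 2])
  expect_lt(rel_err(ngh, g$head$W[, 2]), 1e-5)
})

test_that("softmax probabilities always sum to one", {
  set.seed(44)
  z <- matrix(rnorm(50, sd = 10), 10, 5)
  expect_true(all(abs(rowSums(ecgfusion:::softmax(z)) - 1) < 1e-6))
})

test_that("SMOTE balances classes on segments between minority originals", {
  set.seed(55)
  X <- rbind(matrix(rnorm(20, 0), 10, 2), matrix(rnorm(8, 5), 4, 2))
  y <- c(rep("a", 10), rep("b", 4))
  out <- smote_oversample(X, y, k = 3, seed = 9)
  expect_equal(unname(table(out$y)), c(10, 10), ignore_attr = TRUE)
  # originals preserved in place
  expect_identical(out$X[1:14, ], X)
  expect_identical(which(out$synthetic), 15:20)
  # every synthetic point lies on a segment between two minority points
  minority <- X[11:14, ]
  for (i in 15:20) {
    s <- out$X[i, ]
    on_some_segment <- FALSE
    for (a in 1:3) for (b in (a + 1):4) {
      ab <- minority[b, ] - minority[a, ]
      t <- sum((s - minority[a, ]) * ab) / sum(ab^2)
      if (t >= -1e-9 && t <= 1 + 1e-9 &&
          sqrt(sum((minority[a, ] + t * ab - s)^2)) < 1e-9) {
        on_some_segment <- TRUE
      }
    }
    expect_true(on_some_segment)
  }
  # balanced input returned unchanged
  bal <- smote_oversample(X[c(1:4, 11:14), ], rep(c("a", "b"), each = 4))
  expect_identical(bal$X, X[c(1:4, 11:14), ])
  expect_error(smote_oversample(X[1:11, ], c(rep("a", 10), "b")), "at least 2")
  expect_warning(smote_oversample(X, y, k = 5, seed = 1), "reducing k")
})

test_that("SpecAugment masks exactly the stated bands, reproducibly", {
  img <- array(runif(64 * 64 * 3), c(64, 64, 3))
  expect_identical(spec_augment(img, 0, 0, max_width = 5, seed = 1), img)
  one <- spec_augment(img, n_time_masks = 1, n_freq_masks = 0,
                      max_width = 10, seed = 7)
  changed_cols <- which(apply(one != img, 2, any))
  expect_lte(length(changed_cols), 10)
  expect_identical(changed_cols, seq(min(changed_cols), max(changed_cols)))
  expect_true(all(one[, changed_cols, ] == mean(img)))
  expect_identical(spec_augment(img, 2, 2, 10, seed = 3),
                   spec_augment(img, 2, 2, 10, seed = 3))
})

test_that("ensemble aggregation is a convex combination with stated tie-breaks", {
  p1 <- matrix(c(0.9, 0.1), 1, dimnames = list(NULL, c("le_negative", "le_positive")))
  p2 <- matrix(c(0.2, 0.8), 1, dimnames = list(NULL, c("le_negative", "le_positive")))
  agg <- ensemble_predict(p1, p2, ensemble_weights(0.5, 0.5))
  expect_equal(unname(agg$probs[1, ]), c(0.55, 0.45))
  expect_equal(agg$label, "le_negative")
  # identical inputs pass through for any weights
  same <- ensemble_predict(p1, p1, ensemble_weights(0.3, 0.7))
  expect_equal(same$probs, p1)
  # degenerate weights select one subsystem
  only1 <- ensemble_predict(p1, p2, ensemble_weights(1, 0))
  expect_equal(only1$probs, p1)
  # exact tie resolves toward the positive class
  tie <- ensemble_predict(matrix(c(0.5, 0.5), 1), matrix(c(0.5, 0.5), 1),
                          ensemble_weights(0.5, 0.5))
  expect_equal(tie$label, "1")   # unnamed columns: first column
  tie2 <- ensemble_predict(
    matrix(c(0.5, 0.5), 1, dimnames = list(NULL, c("le_negative", "le_positive"))),
    matrix(c(0.5, 0.5), 1, dimnames = list(NULL, c("le_negative", "le_positive"))))
  expect_equal(tie2$label, "le_positive")
  # probability rows keep summing to 1
  expect_equal(rowSums(agg$probs), 1)
  expect_error(ensemble_weights(0.6, 0.6), "sum to 1")
  expect_error(ensemble_predict(p1, p2[, 2:1]), "class sets")
})

test_that("subsystem training is deterministic and learns separable data", {
  ds <- small_dataset()
  labels <- factor(vapply(ds, `[[`, character(1), "label"))
  feats <- lapply(ds, function(r) extract_features(r$trace))
  cfg <- train_config(epochs = 6, seed = 77)
  m_a <- train_subsystem1(feats, labels, cfg)
  m_b <- train_subsystem1(feats, labels, cfg)
  expect_identical(m_a$params, m_b$params)
  expect_error(train_subsystem1(feats, factor(rep("x", length(feats)))),
               "2 classes")
})

test_that("random initialization yields near-uniform softmax (loss about ln 2)", {
  ds <- small_dataset()
  labels <- factor(vapply(ds, `[[`, character(1), "label"))
  n_pad <- max(vapply(ds, function(r) nrow(extract_features(r$trace)), integer(1)))
  feats <- lapply(ds, function(r) {
    m <- extract_features(r$trace)
    rbind(m, matrix(0, n_pad - nrow(m), 5))
  })
  scaler <- ecgfusion:::fit_feature_scaler(feats)
  params <- ecgfusion:::subsystem1_params(2, seed = 123)
  probs <- t(vapply(feats, function(m) {
    ecgfusion:::s1_forward(params, ecgfusion:::apply_scaler(m, scaler))$probs
  }, numeric(2)))
  loss <- ecgfusion:::cross_entropy(probs, as.integer(labels))
  expect_lt(abs(loss - log(2)), 0.2)
})
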