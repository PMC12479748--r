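# Subsystem 2: compact convolutional spectrogram classifier.
#
# The input contract matches the published preprocessing (224 x 224 x 3
# log-Mel spectrogram images in [0, 1]); the classifier itself is a compact
# trainable CNN rather than a large pretrained audio transformer, with the
# same two-phase schedule (phase 1: encoder frozen, head only; phase 2: full
# fine-tuning), AdamW, SpecAugment-style masking, early stopping and
# best-checkpoint retention. An external model following the same input
# contract can be plugged in wherever a `subsystem2_model` is accepted by
# implementing a `predict` method.
#
# Topology: mean over the three (identical) channels -> fixed anisotropic
# average-pool stem (224 x 224 -> 28 frequency x 112 time cells; time is
# pooled only 2x so heatmaps keep beat-scale resolution, ~0.1 s per cell on a
# 10 s record) -> conv 3x3 (1 -> 8) + ReLU + max-pool 2 (-> 14 x 56) ->
# conv 3x3 (8 -> 16) + ReLU -> conv 3x3 (16 -> 16) + ReLU (the Grad-CAM
# target layer; its receptive field spans ~0.5 s, enough to tell a widened
# QRS burst from a narrow one) -> global average pool -> dense head ->
# softmax.

S2_ROWS <- 28L
S2_COLS <- 112L
S2_C1 <- 8L
S2_C2 <- 16L
S2_C3 <- 16L

subsystem2_params <- function(n_classes, seed) {
  set.seed(seed)
  list(conv1 = list(W = he_init(9, S2_C1, fan_in = 9), b = rep(0, S2_C1)),
       conv2 = list(W = he_init(9 * S2_C1, S2_C2, fan_in = 9 * S2_C1),
                    b = rep(0, S2_C2)),
       conv3 = list(W = he_init(9 * S2_C2, S2_C3, fan_in = 9 * S2_C2),
                    b = rep(0, S2_C3)),
       # zero-initialized head: uniform softmax at initialization
       head = list(W = matrix(0, S2_C3, n_classes), b = rep(0, n_classes)))
}

# Block average pooling of a matrix by integer factors (fr rows, fc cols).
pool_block <- function(plane, fr, fc) {
  m <- matrix(colMeans(matrix(plane, nrow = fr)), nrow = nrow(plane) / fr)
  t(matrix(colMeans(matrix(t(m), nrow = fc)), nrow = ncol(plane) / fc))
}

# Fixed stem: channel mean then block average pooling to S2_ROWS x S2_COLS.
s2_stem <- function(img) {
  plane <- if (length(dim(img)) == 3) {
    (img[, , 1] + img[, , 2] + img[, , 3]) / 3
  } else img
  fr <- nrow(plane) / S2_ROWS; fc <- ncol(plane) / S2_COLS
  stopifnot(fr == round(fr), fc == round(fc))
  pool_block(plane, fr, fc)
}

# im2col index table for 3x3 same-padding convolution on an h x w grid with C
# channels. Index 0 marks zero padding.
im2col_index <- function(h, w, C) {
  key <- paste(h, w, C, sep = "x")
  env <- im2col_cache
  if (!is.null(env[[key]])) return(env[[key]])
  coords <- expand.grid(r = seq_len(h), c = seq_len(w))
  offs <- expand.grid(dr = -1:1, dc = -1:1)
  idx <- matrix(0L, h * w, 9L * C)
  col <- 0L
  for (ch in seq_len(C)) {
    base <- (ch - 1L) * h * w
    for (k in seq_len(9)) {
      col <- col + 1L
      rr <- coords$r + offs$dr[k]
      cc <- coords$c + offs$dc[k]
      ok <- rr >= 1 & rr <= h & cc >= 1 & cc <= w
      idx[ok, col] <- base + (cc[ok] - 1L) * h + rr[ok]
    }
  }
  env[[key]] <- idx
  idx
}
im2col_cache <- new.env(parent = emptyenv())

conv_forward <- function(x, W, b, h, w, C_in) {
  idx <- im2col_index(h, w, C_in)
  v <- c(0, as.numeric(x))   # position 1 = padding zero
  patches <- matrix(v[idx + 1L], nrow = h * w)
  z <- sweep(patches %*% W, 2, b, "+")
  list(out = array(z, c(h, w, ncol(W))), patches = patches,
       idx = idx, h = h, w = w, C_in = C_in)
}

conv_backward <- function(dY, cache, W) {
  n_pix <- cache$h * cache$w
  dZ <- matrix(dY, n_pix)
  dW <- t(cache$patches) %*% dZ
  db <- colSums(dZ)
  dP <- dZ %*% t(W)
  dxv <- numeric(n_pix * cache$C_in + 1L)
  for (k in seq_len(ncol(dP))) {
    tgt <- cache$idx[, k] + 1L
    dxv[tgt] <- dxv[tgt] + dP[, k]
  }
  list(dx = array(dxv[-1L], c(cache$h, cache$w, cache$C_in)), dW = dW, db = db)
}

pool2_forward <- function(x) {
  h <- dim(x)[1]; w <- dim(x)[2]; C <- dim(x)[3]
  ho <- h %/% 2L; wo <- w %/% 2L
  ro <- seq(1L, 2L * ho, by = 2L); re <- ro + 1L
  co <- seq(1L, 2L * wo, by = 2L); ce <- co + 1L
  # linear (within-plane) indices of the four 2x2 cell members
  I <- function(r, c) outer(r, (c - 1L) * h, `+`)
  I11 <- I(ro, co); I21 <- I(re, co); I12 <- I(ro, ce); I22 <- I(re, ce)
  out <- array(0, c(ho, wo, C)); arg <- array(0L, c(ho, wo, C))
  for (ch in seq_len(C)) {
    m <- x[, , ch]
    m11 <- m[ro, co, drop = FALSE]; m21 <- m[re, co, drop = FALSE]
    m12 <- m[ro, ce, drop = FALSE]; m22 <- m[re, ce, drop = FALSE]
    mx <- pmax(m11, m21, m12, m22)
    # tie priority matches column-major which.max: (1,1),(2,1),(1,2),(2,2)
    a <- ifelse(mx == m11, I11, ifelse(mx == m21, I21,
                ifelse(mx == m12, I12, I22)))
    out[, , ch] <- mx
    arg[, , ch] <- a
  }
  list(out = out, arg = arg, h_in = h, w_in = w, C = C)
}

pool2_backward <- function(dY, cache) {
  dx <- array(0, c(cache$h_in, cache$w_in, cache$C))
  for (ch in seq_len(cache$C)) {
    plane <- matrix(0, cache$h_in, cache$w_in)
    pos <- cache$arg[, , ch]
    plane[as.vector(pos)] <- plane[as.vector(pos)] + as.vector(dY[, , ch])
    dx[, , ch] <- plane
  }
  dx
}

s2_forward <- function(params, x_stem) {
  c1 <- conv_forward(x_stem, params$conv1$W, params$conv1$b,
                     S2_ROWS, S2_COLS, 1L)
  a1 <- pmax(c1$out, 0)
  p1 <- pool2_forward(a1)
  c2 <- conv_forward(p1$out, params$conv2$W, params$conv2$b,
                     S2_ROWS %/% 2L, S2_COLS %/% 2L, S2_C1)
  a2 <- pmax(c2$out, 0)
  c3 <- conv_forward(a2, params$conv3$W, params$conv3$b,
                     S2_ROWS %/% 2L, S2_COLS %/% 2L, S2_C2)
  a3 <- pmax(c3$out, 0)
  gap <- apply(a3, 3, mean)
  logits <- drop(gap %*% params$head$W) + params$head$b
  list(logits = logits, probs = drop(softmax(logits)),
       cache = list(c1 = c1, a1 = a1, p1 = p1, c2 = c2, a2 = a2,
                    c3 = c3, a3 = a3, gap = gap))
}

s2_backward <- function(params, cache, dlogits, head_only = FALSE) {
  gap <- cache$gap
  grads <- list(head = list(W = outer(gap, dlogits), b = dlogits))
  if (head_only) return(grads)
  dgap <- drop(params$head$W %*% dlogits)
  n_pix <- prod(dim(cache$a3)[1:2])
  dA3 <- array(rep(dgap / n_pix, each = n_pix), dim(cache$a3))
  dC3 <- dA3 * (cache$c3$out > 0)
  b3 <- conv_backward(dC3, cache$c3, params$conv3$W)
  dC2 <- b3$dx * (cache$c2$out > 0)
  b2 <- conv_backward(dC2, cache$c2, params$conv2$W)
  dP1 <- pool2_backward(b2$dx, cache$p1)
  dC1 <- dP1 * (cache$c1$out > 0)
  b1 <- conv_backward(dC1, cache$c1, params$conv1$W)
  grads$conv1 <- list(W = b1$dW, b = b1$db)
  grads$conv2 <- list(W = b2$dW, b = b2$db)
  grads$conv3 <- list(W = b3$dW, b = b3$db)
  grads
}

#' SpecAugment-style masking of a spectrogram image
#'
#' Sets randomly placed horizontal (frequency) and vertical (time) bands to
#' the image mean; all other cells are untouched. Reproducible from `seed`.
#'
#' @param img a `spectrogram_image` (H x W or H x W x 3 array; rows =
#'   frequency, columns = time).
#' @param n_time_masks,n_freq_masks number of masked bands per axis.
#' @param max_width maximum band width in pixels (each band's width is drawn
#'   uniformly from 1..max_width).
#' @param seed integer seed.
#' @return masked image of the same shape.
#' @export
spec_augment <- function(img, n_time_masks = 2, n_freq_masks = 2,
                         max_width = 20, seed = 1L) {
  d <- dim(img)
  H <- d[1]; W <- d[2]
  if (max_width >= W || max_width >= H) {
    abort_field("max_width", "must be smaller than both image dimensions")
  }
  set.seed(seed)
  fill <- mean(img)
  out <- img
  if (n_time_masks > 0) for (i in seq_len(n_time_masks)) {
    w <- sample.int(max_width, 1)
    start <- sample.int(W - w + 1L, 1)
    if (length(d) == 3) out[, start:(start + w - 1L), ] <- fill
    else out[, start:(start + w - 1L)] <- fill
  }
  if (n_freq_masks > 0) for (i in seq_len(n_freq_masks)) {
    w <- sample.int(max_width, 1)
    start <- sample.int(H - w + 1L, 1)
    if (length(d) == 3) out[start:(start + w - 1L), , ] <- fill
    else out[start:(start + w - 1L), ] <- fill
  }
  out
}

#' Train subsystem 2 (compact spectrogram classifier)
#'
#' Two-phase schedule: phase 1 trains the classification head with the
#' convolutional encoder frozen; phase 2 fine-tunes everything. Cross-entropy
#' loss, AdamW, SpecAugment-style masking on the training images, early
#' stopping on validation loss with best-checkpoint retention.
#'
#' @param images list of 224 x 224 (x3) spectrogram images in \[0, 1\].
#' @param labels factor or character class labels.
#' @param cfg a [train_config()]; default batch size 16.
#' @param phase1_epochs head-only warm-up epochs.
#' @param augment apply SpecAugment masking during training? Off by default
#'   for the compact from-scratch model: with abundant synthetic data it does
#'   not overfit, and beat-scale time masks blur the attention maps the
#'   region metrics evaluate. Enable it when fine-tuning a large plug-in
#'   model.
#' @return A `subsystem2_model` with parameters, class levels and history.
#' @export
train_subsystem2 <- function(images, labels,
                             cfg = train_config(learning_rate = 1e-2,
                                                batch_size = 16, epochs = 60,
                                                patience = 10),
                             phase1_epochs = 3, augment = FALSE) {
  labels <- as.factor(labels)
  if (nlevels(labels) < 2) stop("training data must contain at least 2 classes", call. = FALSE)
  val_idx <- stratified_split(labels, test_fraction = cfg$validation_fraction,
                              seed = derive_seed(cfg$seed, "s2-val"))$test
  tr_idx <- setdiff(seq_along(images), val_idx)
  yi_val <- as.integer(labels[val_idx])
  yi_tr <- as.integer(labels[tr_idx])
  tr_images <- images[tr_idx]

  # per-pixel standardization of the pooled stem, fitted on the (unaugmented)
  # training split; without it the mostly-at-dB-floor images yield feature
  # magnitudes far below weight scale and optimization stalls
  raw_stems <- lapply(tr_images, s2_stem)
  scaler <- local({
    arr <- simplify2array(raw_stems)
    mu <- apply(arr, c(1, 2), mean)
    # single global scale: per-pixel sd is near zero over most of the image
    # and would explode augmented (masked) values there
    s <- stats::sd(sweep(arr, c(1, 2), mu))
    list(mean = mu, sd = max(s, 1e-6))
  })
  Xval <- lapply(images[val_idx], function(im) (s2_stem(im) - scaler$mean) / scaler$sd)

  params <- subsystem2_params(nlevels(labels), derive_seed(cfg$seed, "s2-init"))
  opt <- adamw_init(params)
  history <- data.frame()
  best <- list(loss = Inf, params = params, epoch = 0L)
  wait <- 0L
  set.seed(derive_seed(cfg$seed, "s2-shuffle"))

  evaluate <- function(params, X, yi) {
    probs <- t(vapply(X, function(x) s2_forward(params, x)$probs,
                      numeric(nlevels(labels))))
    list(loss = cross_entropy(probs, yi), acc = mean(max.col(probs) == yi))
  }

  for (epoch in seq_len(cfg$epochs)) {
    head_only <- epoch <= phase1_epochs
    Xtr <- lapply(seq_along(tr_images), function(i) {
      im <- tr_images[[i]]
      if (augment) {
        im <- spec_augment(im, seed = derive_seed(cfg$seed,
                                                  sprintf("aug-%d-%d", epoch, i)))
      }
      (s2_stem(im) - scaler$mean) / scaler$sd
    })
    ord <- sample(length(Xtr))
    for (batch in split(ord, ceiling(seq_along(ord) / cfg$batch_size))) {
      grads <- NULL
      for (i in batch) {
        fw <- s2_forward(params, Xtr[[i]])
        dlogits <- fw$probs
        dlogits[yi_tr[i]] <- dlogits[yi_tr[i]] - 1
        grads <- grad_add(grads, s2_backward(params, fw$cache, dlogits,
                                             head_only = head_only))
      }
      grads <- grad_scale(grads, 1 / length(batch))
      step <- adamw_step(params, grads, opt, cfg$learning_rate, cfg$weight_decay)
      params <- step$params; opt <- step$opt
    }
    tr_m <- evaluate(params, Xtr, yi_tr)
    va_m <- evaluate(params, Xval, yi_val)
    history <- rbind(history,
                     data.frame(epoch = epoch, phase = if (head_only) 1L else 2L,
                                train_loss = tr_m$loss, train_acc = tr_m$acc,
                                val_loss = va_m$loss, val_acc = va_m$acc))
    if (va_m$loss < best$loss - 1e-9) {
      best <- list(loss = va_m$loss, params = params, epoch = epoch)
      wait <- 0L
    } else if (!head_only) {
      wait <- wait + 1L
      if (wait >= cfg$patience) break
    }
  }
  structure(list(params = best$params, levels = levels(labels),
                 scaler = scaler, history = history, best_epoch = best$epoch,
                 config = cfg),
            class = "subsystem2_model")
}

s2_input <- function(model, im) {
  x <- s2_stem(im)
  if (!is.null(model$scaler)) x <- (x - model$scaler$mean) / model$scaler$sd
  x
}

#' Predict class probabilities with subsystem 2
#'
#' @param object a `subsystem2_model`.
#' @param newdata list of 224 x 224 (x3) spectrogram images.
#' @param ... unused.
#' @return matrix n x n_classes of probabilities (columns named by class).
#' @export
predict.subsystem2_model <- function(object, newdata, ...) {
  probs <- t(vapply(newdata, function(im) {
    s2_forward(object$params, s2_input(object, im))$probs
  }, numeric(length(object$levels))))
  colnames(probs) <- object$levels
  probs
}
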