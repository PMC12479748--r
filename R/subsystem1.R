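# Subsystem 1: feature-matrix classifier.
#
# Topology: per-beat feature matrix (time x 5, z-scored per column) -> channel
# lift (5 -> 32) -> residual block (32) -> max-pool/2 -> projection (32 -> 64)
# -> residual block (64) -> max-pool/2 -> projection (64 -> 128) -> residual
# block (128, no pooling after the last block) -> BiRNN encoder -> BiRNN
# decoder -> time-averaged logits -> softmax. Channel widths 32/64/128 and
# the pool-after-first-two-blocks layout follow the reference topology; the
# channel jumps between blocks use 1x1 projections so the skip addition
# inside each block stays shape-compatible.

S1_CHANNELS <- c(32L, 64L, 128L)
S1_HIDDEN <- 16L

subsystem1_params <- function(n_classes, seed) {
  set.seed(seed)
  C <- S1_CHANNELS
  list(lift = list(W = he_init(5, C[1], fan_in = 5), b = rep(0, C[1])),
       block1 = resnet_block_params(C[1]),
       proj1 = list(W = he_init(C[1], C[2]), b = rep(0, C[2])),
       block2 = resnet_block_params(C[2]),
       proj2 = list(W = he_init(C[2], C[3]), b = rep(0, C[3])),
       block3 = resnet_block_params(C[3]),
       enc = birnn_params(C[3], S1_HIDDEN, S1_HIDDEN),
       dec = local({
         # zero-initialized classifier output: logits start at 0, so the
         # softmax is exactly uniform at initialization
         d <- birnn_params(S1_HIDDEN, S1_HIDDEN, n_classes)
         d$U[] <- 0
         d
       }))
}

s1_forward <- function(params, x, training = FALSE) {
  l <- dense_forward(x, params$lift$W, params$lift$b)
  b1 <- resnet_block_fwd(l$out, params$block1, training)
  p1 <- pool_forward(b1$out)
  j1 <- dense_forward(p1$out, params$proj1$W, params$proj1$b)
  b2 <- resnet_block_fwd(j1$out, params$block2, training)
  p2 <- pool_forward(b2$out)
  j2 <- dense_forward(p2$out, params$proj2$W, params$proj2$b)
  b3 <- resnet_block_fwd(j2$out, params$block3, training)
  e <- birnn_fwd(b3$out, params$enc)
  d <- birnn_fwd(e$out, params$dec)
  logits <- colMeans(d$out)
  list(logits = logits, probs = drop(softmax(logits)),
       cache = list(l = l, b1 = b1, p1 = p1, j1 = j1, b2 = b2, p2 = p2,
                    j2 = j2, b3 = b3, e = e, d = d),
       bn_updates = list(block1 = b1$p, block2 = b2$p, block3 = b3$p))
}

s1_backward <- function(params, cache, dlogits) {
  T_ <- nrow(cache$d$out)
  dY <- matrix(dlogits, T_, length(dlogits), byrow = TRUE) / T_
  dd <- birnn_bwd(dY, cache$d, params$dec)
  de <- birnn_bwd(dd$dx, cache$e, params$enc)
  db3 <- resnet_block_bwd(de$dx, cache$b3, params$block3)
  dj2 <- dense_backward(db3$dx, cache$j2, params$proj2$W)
  dp2 <- pool_backward(dj2$dx, cache$p2, ncol(dj2$dx))
  db2 <- resnet_block_bwd(dp2, cache$b2, params$block2)
  dj1 <- dense_backward(db2$dx, cache$j1, params$proj1$W)
  dp1 <- pool_backward(dj1$dx, cache$p1, ncol(dj1$dx))
  db1 <- resnet_block_bwd(dp1, cache$b1, params$block1)
  dl <- dense_backward(db1$dx, cache$l, params$lift$W)
  list(lift = list(W = dl$dW, b = dl$db),
       block1 = db1$grads,
       proj1 = list(W = dj1$dW, b = dj1$db),
       block2 = db2$grads,
       proj2 = list(W = dj2$dW, b = dj2$db),
       block3 = db3$grads,
       enc = de$grads,
       dec = dd$grads)
}

# z-scoring statistics fitted on the training matrices (per column, over all
# rows including pads; the pad indicator survives as a shifted constant).
fit_feature_scaler <- function(matrices) {
  all <- do.call(rbind, matrices)
  mu <- colMeans(all)
  sd <- apply(all, 2, stats::sd)
  sd[sd < 1e-9] <- 1
  list(mean = mu, sd = sd)
}

apply_scaler <- function(m, scaler) {
  sweep(sweep(m, 2, scaler$mean), 2, scaler$sd, "/")
}

#' Train subsystem 1 (residual blocks + BiRNN encoder-decoder)
#'
#' He-normal initialization, AdamW with decoupled weight decay, cross-entropy
#' loss, per-epoch train/validation accuracy history, early stopping on
#' validation loss with best-checkpoint retention. Class imbalance in the
#' training split is corrected with [smote_oversample()] on the flattened,
#' zero-padded feature matrices before fitting.
#'
#' @param matrices list of N x 5 feature matrices (one per record).
#' @param labels factor or character class labels.
#' @param cfg a [train_config()].
#' @param apply_smote balance the training split with SMOTE?
#' @param n_restarts number of random initializations; the fit with the best
#'   validation loss is kept. Small recurrent networks occasionally converge
#'   to a poor basin from an unlucky initialization; two restarts make the
#'   fit reliable at little cost.
#' @return A `subsystem1_model`: parameters, feature scaler, class levels,
#'   padded length, training history.
#' @export
train_subsystem1 <- function(matrices, labels, cfg = train_config(),
                             apply_smote = TRUE, n_restarts = 2) {
  split_seed <- derive_seed(cfg$seed, "s1-val")
  fits <- lapply(seq_len(max(1, n_restarts)), function(r) {
    cfg_r <- cfg
    cfg_r$seed <- derive_seed(cfg$seed, sprintf("restart-%d", r))
    train_subsystem1_once(matrices, labels, cfg_r, apply_smote, split_seed)
  })
  losses <- vapply(fits, function(f) min(f$history$val_loss), numeric(1))
  best <- fits[[which.min(losses)]]
  best$restart_losses <- losses
  best
}

train_subsystem1_once <- function(matrices, labels, cfg, apply_smote,
                                  split_seed = derive_seed(cfg$seed, "s1-val")) {
  labels <- as.factor(labels)
  if (nlevels(labels) < 2) stop("training data must contain at least 2 classes", call. = FALSE)
  n_pad <- max(vapply(matrices, nrow, integer(1)))
  padded <- lapply(matrices, function(m) rbind(m, matrix(0, n_pad - nrow(m), 5)))

  val_idx <- stratified_split(labels, test_fraction = cfg$validation_fraction,
                              seed = split_seed)$test
  tr_idx <- setdiff(seq_along(padded), val_idx)

  Xtr <- padded[tr_idx]; ytr <- labels[tr_idx]
  if (apply_smote && length(unique(table(ytr))) > 1) {
    flat <- t(vapply(Xtr, as.vector, numeric(n_pad * 5)))
    bal <- smote_oversample(flat, ytr, seed = derive_seed(cfg$seed, "s1-smote"))
    Xtr <- lapply(seq_len(nrow(bal$X)), function(i) matrix(bal$X[i, ], n_pad, 5))
    ytr <- bal$y
  }
  scaler <- fit_feature_scaler(Xtr)
  Xtr <- lapply(Xtr, apply_scaler, scaler = scaler)
  Xval <- lapply(padded[val_idx], apply_scaler, scaler = scaler)
  yval <- labels[val_idx]

  params <- subsystem1_params(nlevels(labels), derive_seed(cfg$seed, "s1-init"))
  opt <- adamw_init(params)
  yi_tr <- as.integer(ytr); yi_val <- as.integer(yval)
  history <- data.frame()
  best <- list(loss = Inf, params = params, epoch = 0L)
  wait <- 0L
  set.seed(derive_seed(cfg$seed, "s1-shuffle"))

  evaluate <- function(params, X, yi) {
    probs <- t(vapply(X, function(x) s1_forward(params, x)$probs,
                      numeric(nlevels(labels))))
    list(loss = cross_entropy(probs, yi),
         acc = mean(max.col(probs) == yi))
  }

  for (epoch in seq_len(cfg$epochs)) {
    ord <- sample(length(Xtr))
    for (batch in split(ord, ceiling(seq_along(ord) / cfg$batch_size))) {
      grads <- NULL
      for (i in batch) {
        fw <- s1_forward(params, Xtr[[i]], training = TRUE)
        for (nm in names(fw$bn_updates)) {
          params[[nm]]$bn1 <- fw$bn_updates[[nm]]$bn1
          params[[nm]]$bn2 <- fw$bn_updates[[nm]]$bn2
        }
        dlogits <- fw$probs
        dlogits[yi_tr[i]] <- dlogits[yi_tr[i]] - 1
        grads <- grad_add(grads, s1_backward(params, fw$cache, dlogits))
      }
      grads <- grad_scale(grads, 1 / length(batch))
      step <- adamw_step(params, grads, opt, cfg$learning_rate, cfg$weight_decay)
      # keep BN running stats (adamw never touches them, but params were rebuilt)
      params <- step$params; opt <- step$opt
    }
    tr_m <- evaluate(params, Xtr, yi_tr)
    va_m <- evaluate(params, Xval, yi_val)
    history <- rbind(history,
                     data.frame(epoch = epoch, train_loss = tr_m$loss,
                                train_acc = tr_m$acc, val_loss = va_m$loss,
                                val_acc = va_m$acc))
    if (va_m$loss < best$loss - 1e-9) {
      best <- list(loss = va_m$loss, params = params, epoch = epoch)
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= cfg$patience) break
    }
  }
  structure(list(params = best$params, scaler = scaler,
                 levels = levels(labels), n_pad = n_pad,
                 history = history, best_epoch = best$epoch, config = cfg),
            class = "subsystem1_model")
}

#' Predict class probabilities with subsystem 1
#'
#' @param object a `subsystem1_model`.
#' @param newdata list of N x 5 feature matrices.
#' @param ... unused.
#' @return matrix n x n_classes of probabilities (columns named by class).
#' @export
predict.subsystem1_model <- function(object, newdata, ...) {
  probs <- t(vapply(newdata, function(m) {
    n_pad <- object$n_pad
    if (nrow(m) < n_pad) m <- rbind(m, matrix(0, n_pad - nrow(m), 5))
    if (nrow(m) > n_pad) m <- m[seq_len(n_pad), , drop = FALSE]
    s1_forward(object$params, apply_scaler(m, object$scaler))$probs
  }, numeric(length(object$levels))))
  colnames(probs) <- object$levels
  probs
}
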