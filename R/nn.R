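# Minimal neural-network primitives with analytic backpropagation.
#
# Everything here is plain R on small dense matrices: the package's two
# classifiers are desk-scale by design, and every backward pass is verified
# against central finite differences in the test suite. Conventions: feature
# matrices are time x channels; dense weights multiply on the right
# (y = x W + b, the row-vector form of the W^T x column notation).

he_init <- function(nrow, ncol, fan_in = nrow) {
  matrix(stats::rnorm(nrow * ncol, sd = sqrt(2 / fan_in)), nrow, ncol)
}

relu <- function(x) pmax(x, 0)

softmax <- function(z) {
  if (is.null(dim(z))) z <- matrix(z, nrow = 1)
  e <- exp(z - apply(z, 1, max))
  e / rowSums(e)
}

# Cross-entropy of softmax probabilities against integer class labels (1-based)
cross_entropy <- function(probs, y) {
  -mean(log(pmax(probs[cbind(seq_along(y), y)], 1e-12)))
}

## ---- dense -----------------------------------------------------------------

dense_forward <- function(x, W, b) {
  list(out = sweep(x %*% W, 2, b, "+"), x = x)
}

dense_backward <- function(dY, cache, W) {
  list(dx = dY %*% t(W),
       dW = t(cache$x) %*% dY,
       db = colSums(dY))
}

## ---- batch normalization ---------------------------------------------------

bn_params <- function(channels) {
  list(gamma = rep(1, channels), beta = rep(0, channels),
       running_mean = rep(0, channels), running_var = rep(1, channels))
}

BN_EPS <- 1e-5
BN_MOMENTUM <- 0.1

# x: n x C. Training mode normalizes with the batch (time-axis) statistics and
# updates running estimates; inference mode uses the stored running statistics.
bn_forward <- function(x, p, training = FALSE) {
  if (training && nrow(x) > 1) {
    mu <- colMeans(x)
    v <- colMeans(sweep(x, 2, mu)^2)
    p$running_mean <- (1 - BN_MOMENTUM) * p$running_mean + BN_MOMENTUM * mu
    p$running_var <- (1 - BN_MOMENTUM) * p$running_var + BN_MOMENTUM * v
  } else {
    mu <- p$running_mean
    v <- p$running_var
  }
  xhat <- sweep(sweep(x, 2, mu), 2, sqrt(v + BN_EPS), "/")
  out <- sweep(sweep(xhat, 2, p$gamma, "*"), 2, p$beta, "+")
  list(out = out, xhat = xhat, mu = mu, var = v, x = x, p = p,
       batch_stats = training && nrow(x) > 1)
}

bn_backward <- function(dY, cache) {
  xhat <- cache$xhat
  inv_sd <- 1 / sqrt(cache$var + BN_EPS)
  dgamma <- colSums(dY * xhat)
  dbeta <- colSums(dY)
  dxhat <- sweep(dY, 2, cache$p$gamma, "*")
  if (cache$batch_stats) {
    n <- nrow(xhat)
    dx <- sweep(dxhat - matrix(colMeans(dxhat), n, ncol(xhat), byrow = TRUE) -
                  sweep(xhat, 2, colMeans(dxhat * xhat), "*"),
                2, inv_sd, "*")
  } else {
    dx <- sweep(dxhat, 2, inv_sd, "*")
  }
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

## ---- residual block (pre-activation) ---------------------------------------

#' Parameters for a residual block
#'
#' The block computes `f(x) + x` with
#' `f(x) = (W2)' relu(BN2((W1)' relu(BN1(x))))` — batch normalization and
#' ReLU precede each weight layer, and the skip connection adds the block
#' input. `W1`, `W2` are square (channels x channels) so the skip addition is
#' well-defined.
#'
#' @param channels channel count.
#' @param seed optional seed for He-normal initialization.
#' @return parameter list (`W1`, `W2`, `bn1`, `bn2`).
#' @export
resnet_block_params <- function(channels, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  list(W1 = he_init(channels, channels),
       W2 = he_init(channels, channels),
       bn1 = bn_params(channels),
       bn2 = bn_params(channels))
}

#' Residual block forward pass
#'
#' @param x numeric matrix, time x channels.
#' @param p parameters from [resnet_block_params()].
#' @param training use batch statistics (`TRUE`) or running statistics
#'   (`FALSE`, the inference default)?
#' @return numeric matrix with the shape of `x`.
#' @export
resnet_block_forward <- function(x, p, training = FALSE) {
  resnet_block_fwd(x, p, training)$out
}

resnet_block_fwd <- function(x, p, training = FALSE) {
  if (!is.matrix(x)) x <- matrix(x, nrow = 1)
  if (ncol(x) != nrow(p$W1)) {
    abort_field("x", sprintf("has %d channels but W1 expects %d",
                             ncol(x), nrow(p$W1)))
  }
  c1 <- bn_forward(x, p$bn1, training)
  a1 <- relu(c1$out)
  z1 <- a1 %*% p$W1
  c2 <- bn_forward(z1, p$bn2, training)
  a2 <- relu(c2$out)
  z2 <- a2 %*% p$W2
  list(out = z2 + x, c1 = c1, a1 = a1, c2 = c2, a2 = a2, x = x,
       p = list(bn1 = c1$p, bn2 = c2$p))  # updated running stats
}

resnet_block_bwd <- function(dY, cache, p) {
  dW2 <- t(cache$a2) %*% dY
  da2 <- dY %*% t(p$W2)
  d2 <- bn_backward(da2 * (cache$c2$out > 0), cache$c2)
  dW1 <- t(cache$a1) %*% d2$dx
  da1 <- d2$dx %*% t(p$W1)
  d1 <- bn_backward(da1 * (cache$c1$out > 0), cache$c1)
  list(dx = d1$dx + dY,
       grads = list(W1 = dW1, W2 = dW2,
                    bn1 = list(gamma = d1$dgamma, beta = d1$dbeta),
                    bn2 = list(gamma = d2$dgamma, beta = d2$dbeta)))
}

## ---- bidirectional RNN -----------------------------------------------------

#' Parameters for a bidirectional tanh RNN
#'
#' Forward net: `hf_t = tanh(W_f x_t + V_f hf_{t-1} + b_f)` over t = 1..T;
#' backward net runs symmetrically from t = T..1; per-step output
#' `y_t = U [hf_t, hb_t] + b_y`. Initial hidden states are zero.
#'
#' @param input_dim,hidden_dim,output_dim dimensions.
#' @param seed optional He-normal seed.
#' @return parameter list.
#' @export
birnn_params <- function(input_dim, hidden_dim, output_dim, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  list(Wf = he_init(input_dim, hidden_dim), Vf = he_init(hidden_dim, hidden_dim),
       bf = rep(0, hidden_dim),
       Wb = he_init(input_dim, hidden_dim), Vb = he_init(hidden_dim, hidden_dim),
       bb = rep(0, hidden_dim),
       U = he_init(2 * hidden_dim, output_dim), by = rep(0, output_dim))
}

#' Bidirectional RNN forward pass
#'
#' @param seq numeric matrix, time x input_dim (T >= 1).
#' @param p parameters from [birnn_params()].
#' @return list with `out` (T x output_dim), `h_forward`, `h_backward`
#'   (T x hidden_dim each).
#' @export
birnn_forward <- function(seq, p) {
  cache <- birnn_fwd(seq, p)
  list(out = cache$out, h_forward = cache$hf, h_backward = cache$hb)
}

birnn_fwd <- function(seq, p) {
  if (!is.matrix(seq)) seq <- matrix(seq, nrow = 1)
  T_ <- nrow(seq); H <- ncol(p$Wf)
  hf <- matrix(0, T_, H); hb <- matrix(0, T_, H)
  prev <- rep(0, H)
  for (t in seq_len(T_)) {
    prev <- tanh(drop(seq[t, ] %*% p$Wf) + drop(prev %*% p$Vf) + p$bf)
    hf[t, ] <- prev
  }
  prev <- rep(0, H)
  for (t in rev(seq_len(T_))) {
    prev <- tanh(drop(seq[t, ] %*% p$Wb) + drop(prev %*% p$Vb) + p$bb)
    hb[t, ] <- prev
  }
  out <- sweep(cbind(hf, hb) %*% p$U, 2, p$by, "+")
  list(out = out, hf = hf, hb = hb, x = seq)
}

birnn_bwd <- function(dY, cache, p) {
  T_ <- nrow(cache$x); H <- ncol(p$Wf)
  dU <- t(cbind(cache$hf, cache$hb)) %*% dY
  dby <- colSums(dY)
  dh <- dY %*% t(p$U)
  dhf <- dh[, seq_len(H), drop = FALSE]
  dhb <- dh[, H + seq_len(H), drop = FALSE]
  dWf <- matrix(0, nrow(p$Wf), H); dVf <- matrix(0, H, H); dbf <- rep(0, H)
  dWb <- matrix(0, nrow(p$Wb), H); dVb <- matrix(0, H, H); dbb <- rep(0, H)
  dx <- matrix(0, T_, nrow(p$Wf))
  # forward net BPTT (t = T..1)
  carry <- rep(0, H)
  for (t in rev(seq_len(T_))) {
    dt <- (dhf[t, ] + carry) * (1 - cache$hf[t, ]^2)
    dWf <- dWf + outer(cache$x[t, ], dt)
    hprev <- if (t > 1) cache$hf[t - 1, ] else rep(0, H)
    dVf <- dVf + outer(hprev, dt)
    dbf <- dbf + dt
    dx[t, ] <- dx[t, ] + drop(p$Wf %*% dt)
    carry <- drop(p$Vf %*% dt)
  }
  # backward net BPTT (t = 1..T)
  carry <- rep(0, H)
  for (t in seq_len(T_)) {
    dt <- (dhb[t, ] + carry) * (1 - cache$hb[t, ]^2)
    dWb <- dWb + outer(cache$x[t, ], dt)
    hprev <- if (t < T_) cache$hb[t + 1, ] else rep(0, H)
    dVb <- dVb + outer(hprev, dt)
    dbb <- dbb + dt
    dx[t, ] <- dx[t, ] + drop(p$Wb %*% dt)
    carry <- drop(p$Vb %*% dt)
  }
  list(dx = dx,
       grads = list(Wf = dWf, Vf = dVf, bf = dbf,
                    Wb = dWb, Vb = dVb, bb = dbb, U = dU, by = dby))
}

## ---- max pooling over time (size 2, stride 2) ------------------------------

pool_forward <- function(x) {
  T_ <- nrow(x)
  n_out <- ceiling(T_ / 2)
  idx <- integer(n_out)
  out <- matrix(0, n_out, ncol(x))
  argmax <- matrix(0L, n_out, ncol(x))
  for (i in seq_len(n_out)) {
    rows <- (2 * i - 1):min(2 * i, T_)
    sub <- x[rows, , drop = FALSE]
    w <- apply(sub, 2, which.max)
    out[i, ] <- sub[cbind(w, seq_len(ncol(x)))]
    argmax[i, ] <- rows[w]
  }
  list(out = out, argmax = argmax, T_in = T_)
}

pool_backward <- function(dY, cache, n_channels) {
  dx <- matrix(0, cache$T_in, n_channels)
  for (i in seq_len(nrow(dY))) {
    dx[cbind(cache$argmax[i, ], seq_len(n_channels))] <-
      dx[cbind(cache$argmax[i, ], seq_len(n_channels))] + dY[i, ]
  }
  dx
}

## ---- AdamW -----------------------------------------------------------------

# Parameters and gradients are nested named lists of numerics; the optimizer
# walks them recursively. Weight decay is decoupled (applied directly to the
# parameter, not through the moments) and skipped for BN/bias leaves.

adamw_init <- function(params) {
  walk <- function(p) {
    if (is.list(p)) return(lapply(p, walk))
    list(m = p * 0, v = p * 0)
  }
  list(state = walk(params), t = 0L)
}

adamw_step <- function(params, grads, opt, lr, weight_decay = 0.01,
                       beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  opt$t <- opt$t + 1L
  t <- opt$t
  walk <- function(p, g, s, path) {
    if (is.list(p)) {
      for (nm in names(p)) {
        if (is.null(g[[nm]])) next
        res <- walk(p[[nm]], g[[nm]], s[[nm]], c(path, nm))
        p[[nm]] <- res$p; s[[nm]] <- res$s
      }
      return(list(p = p, s = s))
    }
    s$m <- beta1 * s$m + (1 - beta1) * g
    s$v <- beta2 * s$v + (1 - beta2) * g^2
    mhat <- s$m / (1 - beta1^t)
    vhat <- s$v / (1 - beta2^t)
    decay <- if (any(c("bn1", "bn2", "gamma", "beta", "bf", "bb", "by", "b") %in% path) ||
                 path[length(path)] %in% c("b", "bf", "bb", "by", "gamma", "beta")) 0 else weight_decay
    p <- p - lr * (mhat / (sqrt(vhat) + eps) + decay * p)
    list(p = p, s = s)
  }
  res <- walk(params, grads, opt$state, character(0))
  list(params = res$p, opt = list(state = res$s, t = t))
}

# Recursive gradient accumulation: a + b elementwise over nested lists.
grad_add <- function(a, b) {
  if (is.null(a)) return(b)
  if (is.list(b)) return(mapply(grad_add, a, b, SIMPLIFY = FALSE))
  a + b
}

grad_scale <- function(g, s) {
  if (is.list(g)) return(lapply(g, grad_scale, s = s))
  g * s
}

#' Training configuration
#'
#' The optimizer is AdamW (decoupled weight decay). The published
#' fine-tuning settings (learning rate 1e-4 for the feature-matrix subsystem,
#' 2e-5 for the spectrogram model, weight decay 0.01) describe fine-tuning of
#' large pretrained networks; the desk-scale from-scratch defaults here use
#' larger learning rates, and the published values remain available through
#' this constructor.
#'
#' @param learning_rate AdamW step size.
#' @param weight_decay decoupled weight decay (skipped for biases and BN).
#' @param batch_size minibatch size.
#' @param epochs maximum epochs.
#' @param patience early-stopping patience on validation loss (epochs).
#' @param validation_fraction share of the training data held out for early
#'   stopping.
#' @param seed RNG seed (initialization, shuffling, augmentation).
#' @return A `train_config` object.
#' @export
train_config <- function(learning_rate = 1e-2, weight_decay = 0.01,
                         batch_size = 32, epochs = 25, patience = 8,
                         validation_fraction = 0.2, seed = 1L) {
  check_number(learning_rate, "learning_rate", 1e-12)
  check_number(weight_decay, "weight_decay", 0)
  check_number(batch_size, "batch_size", 1)
  check_number(epochs, "epochs", 1)
  check_number(patience, "patience", 1)
  check_number(validation_fraction, "validation_fraction", 0, 0.9)
  structure(list(learning_rate = learning_rate, weight_decay = weight_decay,
                 batch_size = as.integer(batch_size), epochs = as.integer(epochs),
                 patience = as.integer(patience),
                 validation_fraction = validation_fraction,
                 seed = as.integer(seed)),
            class = "train_config")
}
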