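# Synthetic Minority Over-sampling Technique.
#
# Each synthetic point is x + u * (x_nn - x) with u ~ Uniform(0, 1) and x_nn
# one of the k nearest minority-class neighbors of x, so every synthetic
# sample lies on a segment between two minority originals. No installed
# package provides SMOTE, so the primitive is implemented here and verified
# by a geometric oracle in the tests.

#' SMOTE oversampling to equalize a binary class imbalance
#'
#' Originals are preserved (and never altered); synthetic minority rows are
#' appended until the classes are balanced. Already-balanced input is
#' returned unchanged.
#'
#' @param X numeric matrix, one sample per row.
#' @param y factor/character labels (2 classes).
#' @param k nearest-neighbor count (reduced with a warning when the minority
#'   class has at most `k` members).
#' @param seed integer seed.
#' @return list with balanced `X`, `y`, and `synthetic` (logical marker).
#' @export
smote_oversample <- function(X, y, k = 5, seed = 1L) {
  y <- as.factor(y)
  if (nlevels(droplevels(y)) != 2) abort_field("y", "must have exactly 2 classes")
  tab <- table(y)
  if (length(unique(tab)) == 1) {
    return(list(X = X, y = y, synthetic = rep(FALSE, nrow(X))))
  }
  minority <- names(which.min(tab))
  min_idx <- which(y == minority)
  n_min <- length(min_idx)
  if (n_min < 2) stop("minority class needs at least 2 samples for SMOTE", call. = FALSE)
  if (n_min <= k) {
    warning(sprintf("minority class has %d samples; reducing k from %d to %d",
                    n_min, k, n_min - 1L))
    k <- n_min - 1L
  }
  need <- max(tab) - n_min
  Xm <- X[min_idx, , drop = FALSE]
  d <- as.matrix(stats::dist(Xm))
  diag(d) <- Inf
  nn <- t(apply(d, 1, function(r) order(r)[seq_len(k)]))
  set.seed(seed)
  base <- sample.int(n_min, need, replace = TRUE)
  pick <- sample.int(k, need, replace = TRUE)
  u <- stats::runif(need)
  synth <- Xm[base, , drop = FALSE] +
    u * (Xm[nn[cbind(base, pick)], , drop = FALSE] - Xm[base, , drop = FALSE])
  list(X = rbind(X, synth),
       y = factor(c(as.character(y), rep(minority, need)), levels = levels(y)),
       synthetic = c(rep(FALSE, nrow(X)), rep(TRUE, need)))
}
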