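# Weighted aggregation of the two subsystems' class probabilities.

#' Ensemble weights
#'
#' @param w1,w2 non-negative weights for subsystems 1 and 2; must sum to 1.
#' @return An `ensemble_weights` object.
#' @export
ensemble_weights <- function(w1 = 0.5, w2 = 0.5) {
  check_number(w1, "w1", 0); check_number(w2, "w2", 0)
  if (abs(w1 + w2 - 1) > 1e-9) abort_field("w1", "weights must sum to 1")
  structure(list(w1 = w1, w2 = w2), class = "ensemble_weights")
}

#' Weighted aggregation of two probability outputs
#'
#' `p = w1 * p1 + w2 * p2`; the label is the argmax, with exact ties broken
#' toward the positive (`le_positive`) class when present, else toward the
#' first class column.
#'
#' @param p1,p2 probability matrices (n x classes, identical column names and
#'   order) or single probability vectors.
#' @param w an [ensemble_weights()].
#' @return list with `probs` (matrix) and `label` (character vector).
#' @export
ensemble_predict <- function(p1, p2, w = ensemble_weights()) {
  if (is.null(dim(p1))) p1 <- matrix(p1, 1, dimnames = list(NULL, names(p1)))
  if (is.null(dim(p2))) p2 <- matrix(p2, 1, dimnames = list(NULL, names(p2)))
  if (!identical(dim(p1), dim(p2)) ||
      (!is.null(colnames(p1)) && !identical(colnames(p1), colnames(p2)))) {
    abort_field("p2", "class sets of p1 and p2 must match")
  }
  if (max(abs(rowSums(p1) - 1)) > 1e-6 || max(abs(rowSums(p2) - 1)) > 1e-6) {
    abort_field("p1", "probability rows must sum to 1")
  }
  p <- w$w1 * p1 + w$w2 * p2
  classes <- colnames(p)
  if (is.null(classes)) classes <- as.character(seq_len(ncol(p)))
  pref <- if ("le_positive" %in% classes) match("le_positive", classes) else 1L
  label <- apply(p, 1, function(r) {
    top <- which(abs(r - max(r)) < 1e-12)
    classes[if (pref %in% top) pref else top[1]]
  })
  list(probs = p, label = label)
}

#' Fit ensemble weights by grid search on validation accuracy
#'
#' @param p1,p2 validation probability matrices from the two subsystems.
#' @param labels true validation labels.
#' @param grid candidate values of `w1`.
#' @return the [ensemble_weights()] maximizing validation accuracy (ties
#'   toward 0.5/0.5).
#' @export
fit_ensemble_weights <- function(p1, p2, labels, grid = seq(0, 1, by = 0.1)) {
  labels <- as.character(labels)
  accs <- vapply(grid, function(w1) {
    mean(ensemble_predict(p1, p2, ensemble_weights(w1, 1 - w1))$label == labels)
  }, numeric(1))
  best <- grid[accs == max(accs)]
  w1 <- best[which.min(abs(best - 0.5))]
  ensemble_weights(w1, 1 - w1)
}
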