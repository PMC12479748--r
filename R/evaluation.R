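# Evaluation protocol: 2x2 confusion counts, sensitivity/specificity/
# accuracy/F1, rank-based AUC, stratified 80/20 splitting, and stratified
# k-fold cross-validation with mean +/- sd reporting.

#' Confusion counts for a binary classifier
#'
#' @param labels true labels (2 classes).
#' @param predictions predicted labels on the same class set.
#' @param positive_class which label counts as positive.
#' @return A `confusion_counts` object: list(tp, fp, tn, fn).
#' @export
confusion <- function(labels, predictions, positive_class) {
  labels <- as.character(labels); predictions <- as.character(predictions)
  if (length(labels) != length(predictions)) {
    abort_field("predictions", "must have the same length as labels")
  }
  pos <- labels == positive_class
  pred_pos <- predictions == positive_class
  structure(list(tp = sum(pos & pred_pos), fp = sum(!pos & pred_pos),
                 tn = sum(!pos & !pred_pos), fn = sum(pos & !pred_pos)),
            class = "confusion_counts")
}

#' Confusion counts from raw integers
#' @param tp,fp,tn,fn non-negative integers.
#' @return A `confusion_counts` object.
#' @export
confusion_counts <- function(tp, fp, tn, fn) {
  for (v in c(tp, fp, tn, fn)) check_number(v, "count", 0)
  structure(list(tp = tp, fp = fp, tn = tn, fn = fn),
            class = "confusion_counts")
}

#' Sensitivity, specificity, accuracy and F1 from confusion counts
#'
#' Sensitivity = TP/(TP+FN); specificity = TN/(TN+FP); accuracy =
#' (TP+TN)/(TP+FN+TN+FP); F1 = 2*precision*recall/(precision+recall) with
#' precision = TP/(TP+FP). Values are returned as percentages at full
#' precision; `digits` controls display rounding only. A zero denominator
#' yields `NA` with a warning.
#'
#' @param c a `confusion_counts` object.
#' @param digits named or single rounding for the percent display columns.
#' @return data.frame with `metric`, `value` (exact percent), `display`
#'   (rounded percent).
#' @export
metrics_from_confusion <- function(c, digits = c(sensitivity = 1, specificity = 0,
                                                 accuracy = 2, f1 = 1)) {
  safe <- function(num, den, what) {
    if (den == 0) {
      warning(sprintf("%s undefined: zero denominator", what))
      return(NA_real_)
    }
    num / den
  }
  sens <- safe(c$tp, c$tp + c$fn, "sensitivity")
  spec <- safe(c$tn, c$tn + c$fp, "specificity")
  acc <- safe(c$tp + c$tn, c$tp + c$fn + c$tn + c$fp, "accuracy")
  prec <- safe(c$tp, c$tp + c$fp, "precision")
  f1 <- if (is.na(prec) || is.na(sens) || prec + sens == 0) NA_real_ else
    2 * prec * sens / (prec + sens)
  vals <- c(sensitivity = sens, specificity = spec, accuracy = acc, f1 = f1) * 100
  if (length(digits) == 1) digits <- stats::setNames(rep(digits, 4), names(vals))
  data.frame(metric = names(vals),
             value = unname(vals),
             display = unname(round(vals, digits[names(vals)])),
             row.names = NULL)
}

#' Area under the ROC curve
#'
#' Rank-statistic (Mann-Whitney) formulation with midranks for ties, which
#' is exactly the trapezoidal integral over all score thresholds.
#'
#' @param scores numeric scores (higher = more positive).
#' @param labels binary labels.
#' @param positive_class the positive label (default: the second sorted
#'   level).
#' @return AUC in \[0, 1\].
#' @export
roc_auc <- function(scores, labels, positive_class = NULL) {
  labels <- as.character(labels)
  classes <- sort(unique(labels))
  if (length(classes) < 2) stop("both classes must be present for AUC", call. = FALSE)
  if (is.null(positive_class)) positive_class <- classes[2]
  pos <- labels == positive_class
  n1 <- sum(pos); n0 <- sum(!pos)
  r <- rank(scores)   # midranks handle ties (= trapezoidal tie averaging)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Stratified train/test split
#'
#' Per-class test counts are `round(class_size * test_fraction)`; indices are
#' disjoint and exhaustive, reproducible from `seed`.
#'
#' @param labels class labels.
#' @param test_fraction fraction held out (default 0.2).
#' @param seed integer seed.
#' @return list with `train` and `test` integer index vectors.
#' @export
stratified_split <- function(labels, test_fraction = 0.2, seed = 1L) {
  labels <- as.factor(labels)
  check_number(test_fraction, "test_fraction", 0, 1)
  if (any(table(labels) < 2)) stop("each class needs at least 2 samples", call. = FALSE)
  set.seed(seed)
  test <- integer(0)
  for (cl in levels(labels)) {
    idx <- which(labels == cl)
    n_test <- round(length(idx) * test_fraction)
    test <- c(test, sample(idx, n_test))
  }
  test <- sort(test)
  list(train = setdiff(seq_along(labels), test), test = test)
}

#' Stratified k-fold cross-validation
#'
#' Folds preserve class proportions to within one sample. All fitting
#' (including any oversampling) must happen inside `fit_predict`, which
#' receives only training indices — the fold's test data never leaks into
#' fitting.
#'
#' @param labels class labels for the full dataset.
#' @param k number of folds (each class must have at least `k` members).
#' @param seed integer seed for fold assignment.
#' @param fit_predict `function(train_idx, test_idx)` returning a list with
#'   `predictions` (labels for `test_idx`) and optionally `scores`
#'   (positive-class probabilities).
#' @param positive_class positive label for the confusion metrics.
#' @return A `cv_report`: per-fold metric data.frame, `mean` and `sd` rows,
#'   fold assignment, seed.
#' @export
kfold_cv <- function(labels, k = 5, seed = 1L, fit_predict,
                     positive_class = "le_positive") {
  labels <- as.factor(labels)
  if (any(table(labels) < k)) stop("each class needs at least k samples", call. = FALSE)
  set.seed(seed)
  fold <- integer(length(labels))
  for (cl in levels(labels)) {
    idx <- sample(which(labels == cl))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  per_fold <- lapply(seq_len(k), function(f) {
    test_idx <- which(fold == f)
    train_idx <- which(fold != f)
    res <- fit_predict(train_idx, test_idx)
    m <- metrics_from_confusion(
      confusion(labels[test_idx], res$predictions, positive_class))
    row <- stats::setNames(as.list(m$value), m$metric)
    row$auc <- if (!is.null(res$scores) &&
                   length(unique(labels[test_idx])) == 2) {
      100 * roc_auc(res$scores, labels[test_idx], positive_class)
    } else NA_real_
    as.data.frame(c(list(fold = f), row))
  })
  tab <- do.call(rbind, per_fold)
  metrics <- setdiff(names(tab), "fold")
  structure(list(per_fold = tab,
                 mean = vapply(tab[metrics], mean, numeric(1), na.rm = TRUE),
                 sd = vapply(tab[metrics], stats::sd, numeric(1)),
                 fold_assignment = fold, k = k, seed = seed),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("%d-fold stratified cross-validation (seed %d)\n", x$k, x$seed))
  print(x$per_fold, row.names = FALSE)
  cat("\nmean:\n"); print(round(x$mean, 2))
  cat("sd:\n"); print(round(x$sd, 2))
  invisible(x)
}
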