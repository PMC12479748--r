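test_that("confusion counts follow the 2x2 contingency definition", {
  y <- rep(c("pos", "neg"), each = 10)
  perfect <- confusion(y, y, "pos")
  expect_equal(unlist(perfect[c("tp", "tn", "fp", "fn")]), c(tp = 10, tn = 10, fp = 0, fn = 0))
  allpos <- confusion(y, rep("pos", 20), "pos")
  expect_equal(unlist(allpos[c("tp", "fp", "tn", "fn")]), c(tp = 10, fp = 10, tn = 0, fn = 0))
  set.seed(1)
  pred <- sample(c("pos", "neg"), 20, replace = TRUE)
  cc <- confusion(y, pred, "pos")
  expect_equal(cc$tp + cc$fp + cc$tn + cc$fn, 20)
  expect_error(confusion(y, pred[1:5], "pos"), "length")
})

test_that("metric formulas are scale-free and swap under class relabeling", {
  c1 <- confusion_counts(tp = 30, fp = 5, tn = 50, fn = 10)
  m1 <- metrics_from_confusion(c1)
  c2 <- confusion_counts(tp = 90, fp = 15, tn = 150, fn = 30)
  m2 <- metrics_from_confusion(c2)
  expect_equal(m1$value, m2$value)
  # flipping the positive class swaps sensitivity and specificity
  flipped <- confusion_counts(tp = 50, fp = 10, tn = 30, fn = 5)
  mf <- metrics_from_confusion(flipped)
  expect_equal(mf$value[mf$metric == "sensitivity"],
               m1$value[m1$metric == "specificity"])
  expect_equal(mf$value[mf$metric == "specificity"],
               m1$value[m1$metric == "sensitivity"])
  expect_warning(bad <- metrics_from_confusion(confusion_counts(tp = 0, fp = 3,
                                                                tn = 5, fn = 0)),
                 "sensitivity undefined")
  expect_true(is.na(bad$value[bad$metric == "sensitivity"]))
})

test_that("rank AUC equals the pair-counting estimator on random instances", {
  expect_equal(roc_auc(c(1, 2, 3, 10), c("n", "n", "p", "p"), "p"), 1)
  expect_equal(roc_auc(rep(0.4, 10), rep(c("n", "p"), 5), "p"), 0.5)
  expect_equal(roc_auc(c(0.1, 0.4, 0.35, 0.8), c("n", "n", "p", "p"), "p"), 0.75)
  set.seed(17)
  for (rep in 1:25) {
    n <- sample(4:50, 1)
    labels <- c("n", "p", sample(c("n", "p"), n - 2, replace = TRUE))
    scores <- sample(seq(0, 1, by = 0.05), n, replace = TRUE)  # ties likely
    expect_equal(roc_auc(scores, labels, "p"),
                 pair_count_auc(scores, labels, "p"),
                 tolerance = 1e-12)
  }
  expect_error(roc_auc(1:4, rep("p", 4)), "both classes")
})

test_that("rank AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(23)
  labels <- sample(c("n", "p"), 60, replace = TRUE, prob = c(0.5, 0.5))
  scores <- rnorm(60) + (labels == "p")
  ref <- as.numeric(pROC::auc(pROC::roc(labels, scores, levels = c("n", "p"),
                                        direction = "<", quiet = TRUE)))
  expect_equal(roc_auc(scores, labels, "p"), ref, tolerance = 1e-12)
})

test_that("stratified splitting is exact, disjoint, exhaustive, reproducible", {
  labels <- rep(c("a", "b"), each = 100)
  sp <- stratified_split(labels, 0.2, seed = 4)
  expect_length(sp$test, 40)
  expect_equal(sum(labels[sp$test] == "a"), 20)
  expect_length(intersect(sp$train, sp$test), 0)
  expect_setequal(c(sp$train, sp$test), seq_along(labels))
  expect_identical(sp, stratified_split(labels, 0.2, seed = 4))
  expect_false(identical(sp, stratified_split(labels, 0.2, seed = 5)))
  expect_error(stratified_split(c("a", "b"), 0.5), "at least 2")
})

test_that("stratified k-fold preserves class balance and reports mean/sd", {
  labels <- factor(rep(c("le_negative", "le_positive"), times = c(23, 27)))
  # constant classifier: per-fold accuracy = that fold's majority fraction
  rep_cv <- kfold_cv(labels, k = 5, seed = 3,
                     fit_predict = function(tr, te) {
                       list(predictions = rep("le_positive", length(te)))
                     })
  fold <- rep_cv$fold_assignment
  for (f in 1:5) {
    for (cl in levels(labels)) {
      per_fold <- sum(labels[fold == f] == cl)
      expect_lte(abs(per_fold - sum(labels == cl) / 5), 1)
    }
    acc_expected <- 100 * mean(labels[fold == f] == "le_positive")
    expect_equal(rep_cv$per_fold$accuracy[f], acc_expected)
  }
  # mean/sd recomputed independently match the report
  expect_equal(rep_cv$mean[["accuracy"]], sum(rep_cv$per_fold$accuracy) / 5,
               tolerance = 1e-12)
  manual_sd <- sqrt(sum((rep_cv$per_fold$accuracy -
                           mean(rep_cv$per_fold$accuracy))^2) / 4)
  expect_equal(rep_cv$sd[["accuracy"]], manual_sd, tolerance = 1e-12)
  expect_error(kfold_cv(factor(c("a", "a", "b")), k = 5,
                        fit_predict = function(tr, te) NULL),
               "at least k")
})
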