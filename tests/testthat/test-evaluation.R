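test_that("stratified splitting preserves class proportions exactly", {
  labs <- rep(c("melanoma", "benign"), each = 250)
  sp <- stratified_split(labs, 0.7, seed = 1)
  expect_length(sp$train, 350)
  expect_length(sp$test, 150)
  expect_equal(sum(labs[sp$train] == "melanoma"), 175)
  expect_setequal(c(sp$train, sp$test), seq_along(labs))

  sp2 <- stratified_split(labs, 0.7, seed = 1)
  expect_identical(sp, sp2)

  expect_error(stratified_split(labs, 1.0), "degenerate")
  expect_error(stratified_split(rep("melanoma", 10), 0.7), "both classes")
})

test_that("confusion counts follow their definitions", {
  truth <- c(rep("melanoma", 71), rep("benign", 79))
  perfect <- confusion_matrix2(truth, truth)
  expect_equal(perfect[c("tp", "fn", "fp", "tn")],
               list(tp = 71, fn = 0, fp = 0, tn = 79))

  pred <- truth
  pred[1:4] <- "benign"          # 4 melanoma missed
  pred[72:73] <- "melanoma"      # 2 benign called melanoma
  cm <- confusion_matrix2(truth, pred)
  expect_equal(cm[c("tp", "fn", "fp", "tn")],
               list(tp = 67, fn = 4, fp = 2, tn = 77))

  all_ben <- confusion_matrix2(rep(c("melanoma", "benign"), each = 5),
                               rep("benign", 10))
  expect_equal(all_ben[c("tp", "fn", "fp", "tn")],
               list(tp = 0, fn = 5, fp = 0, tn = 5))

  expect_error(confusion_matrix2(truth, pred[-1]), "equal length")
})

test_that("metrics agree with the per-definition oracle on random predictions", {
  set.seed(71)
  for (rep in 1:20) {
    n <- sample(20:60, 1)
    truth <- sample(c("melanoma", "benign"), n, replace = TRUE)
    if (length(unique(truth)) < 2) next
    pred <- sample(c("melanoma", "benign"), n, replace = TRUE)
    m <- classification_metrics(confusion_matrix2(truth, pred))
    o <- oracle_metrics(truth, pred)
    expect_equal(m$unrounded$accuracy, o$accuracy, tolerance = 1e-12)
    expect_equal(unname(m$unrounded$melanoma), unname(o$melanoma),
                 tolerance = 1e-12)
    expect_equal(unname(m$unrounded$benign), unname(o$benign),
                 tolerance = 1e-12)
    expect_equal(unname(m$unrounded$macro), unname(o$macro),
                 tolerance = 1e-12)
  }
})

test_that("swapping class roles swaps per-class metrics, fixing accuracy/macro", {
  m <- classification_metrics(confusion_from_counts(tp = 67, fn = 4,
                                                    fp = 2, tn = 77))
  swapped <- classification_metrics(confusion_from_counts(tp = 77, fn = 2,
                                                          fp = 4, tn = 67))
  expect_equal(m$unrounded$melanoma, swapped$unrounded$benign)
  expect_equal(m$unrounded$benign, swapped$unrounded$melanoma)
  expect_equal(m$unrounded$accuracy, swapped$unrounded$accuracy)
  expect_equal(m$unrounded$macro, swapped$unrounded$macro)
})

test_that("edge confusion matrices are handled", {
  diag <- classification_metrics(confusion_from_counts(10, 0, 0, 15))
  expect_true(all(unlist(diag$report[, -1]) == 100))
  expect_false(diag$zero_division)

  none_called <- classification_metrics(confusion_from_counts(0, 5, 0, 5))
  expect_true(none_called$zero_division)
  expect_equal(unname(none_called$unrounded$melanoma["precision"]), 0)

  identical_macro <- classification_metrics(confusion_from_counts(5, 5, 5, 5))
  expect_equal(unname(identical_macro$unrounded$macro["precision"]), 50)

  expect_error(classification_metrics(confusion_from_counts(0, 0, 0, 0)),
               "empty")
  expect_error(confusion_from_counts(-1, 0, 0, 2), "non-negative")
})

test_that("ROC and PR sweeps behave at the extremes", {
  truth <- rep(c("melanoma", "benign"), each = 10)
  sep <- c(seq(0.9, 0.99, length.out = 10), seq(0.01, 0.1, length.out = 10))
  roc <- roc_points(truth, sep)
  expect_equal(roc$auc, 1)
  expect_true(any(roc$points$fpr == 0 & roc$points$tpr == 1))
  expect_true(all(diff(roc$points$fpr) >= 0))
  expect_equal(pr_points(truth, sep)$auc, 1, tolerance = 1e-9)

  rev_roc <- roc_points(truth, 1 - sep)
  expect_equal(rev_roc$auc, 0)

  expect_error(roc_points(rep("melanoma", 5), runif(5)), "both classes")
})

test_that("label-independent scores give chance-level AUC", {
  set.seed(81)
  truth <- sample(c("melanoma", "benign"), 2000, replace = TRUE)
  scores <- runif(2000)
  expect_equal(roc_points(truth, scores)$auc, 0.5, tolerance = 0.05)
})

test_that("AUC agrees with an independent implementation", {
  skip_if_not_installed("pROC")
  set.seed(91)
  truth <- sample(c("melanoma", "benign"), 80, replace = TRUE)
  scores <- runif(80) + 0.5 * (truth == "melanoma")
  ours <- roc_points(truth, scores)$auc
  ref <- suppressMessages(pROC::auc(pROC::roc(
    response = factor(truth, levels = c("benign", "melanoma")),
    predictor = scores, quiet = TRUE)))
  expect_equal(ours, as.numeric(ref), tolerance = 1e-10)
})
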