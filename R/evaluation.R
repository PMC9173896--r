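#' Stratified train/test split
#'
#' Splits indices so that `round(train_fraction * n_class)` samples of each
#' class land in the training set; the split is seeded, disjoint and
#' exhaustive.
#'
#' @param labels character (or factor) vector with both classes present.
#' @param train_fraction fraction of each class assigned to training.
#' @param seed integer seed.
#' @return list with integer vectors `train` and `test`.
#' @examples
#' labs <- rep(c("melanoma", "benign"), each = 250)
#' sp <- stratified_split(labs, 0.7, seed = 1)
#' c(train = length(sp$train), test = length(sp$test))  # 350 / 150
#' @export
stratified_split <- function(labels, train_fraction = 0.7, seed = 1L) {
  labels <- as.character(labels)
  check_scalar_number(train_fraction, "train_fraction", lower = 0, upper = 1,
                      strict_lower = TRUE)
  if (length(unique(labels)) < 2L) {
    stop("both classes must be present to stratify", call. = FALSE)
  }
  with_seed(seed, {
    train <- integer(0)
    for (cl in sort(unique(labels))) {
      idx <- which(labels == cl)
      n_train <- round(train_fraction * length(idx))
      train <- c(train, sample(idx, n_train))
    }
    train <- sort(train)
    test <- setdiff(seq_along(labels), train)
    if (length(test) == 0L || length(train) == 0L) {
      stop("degenerate split: train or test set is empty", call. = FALSE)
    }
    list(train = train, test = test)
  })
}

#' Two-class confusion matrix (melanoma positive)
#'
#' @param truth,predicted equal-length vectors of `"melanoma"` / `"benign"`.
#' @return an object of class `confusion_matrix2`: list with counts `tp`
#'   (melanoma called melanoma), `fn`, `fp` (benign called melanoma), `tn`.
#' @export
confusion_matrix2 <- function(truth, predicted) {
  truth <- as.character(truth); predicted <- as.character(predicted)
  if (length(truth) != length(predicted)) {
    stop("`truth` and `predicted` must have equal length", call. = FALSE)
  }
  confusion_from_counts(
    tp = sum(truth == "melanoma" & predicted == "melanoma"),
    fn = sum(truth == "melanoma" & predicted == "benign"),
    fp = sum(truth == "benign" & predicted == "melanoma"),
    tn = sum(truth == "benign" & predicted == "benign"))
}

#' @rdname confusion_matrix2
#' @param tp,fn,fp,tn non-negative counts with melanoma as positive class.
#' @export
confusion_from_counts <- function(tp, fn, fp, tn) {
  counts <- c(tp = tp, fn = fn, fp = fp, tn = tn)
  if (any(counts < 0) || any(!is.finite(counts))) {
    stop("confusion counts must be non-negative", call. = FALSE)
  }
  structure(list(tp = tp, fn = fn, fp = fp, tn = tn,
                 total = tp + fn + fp + tn),
            class = "confusion_matrix2")
}

.prf <- function(tp, fp, fn) {
  precision <- if (tp + fp == 0) 0 else tp / (tp + fp)
  recall <- if (tp + fn == 0) 0 else tp / (tp + fn)
  f <- if (precision + recall == 0) 0 else
    2 * precision * recall / (precision + recall)
  c(precision = precision, recall = recall, f_score = f)
}

#' Classification metrics from a confusion matrix
#'
#' Per-class precision, recall and F-score (melanoma and benign, each
#' treated in turn as the positive class), overall accuracy, and macro
#' (unweighted mean over the two classes) averages.  Values are in percent;
#' `$report` carries them rounded half-up to 2 decimals in the conventional
#' table layout (rows Melanoma / Benign / Average), while the unrounded
#' values are kept alongside.  Metrics with a zero denominator are reported
#' as 0 and flagged via `zero_division`.
#'
#' @param cm a [confusion_matrix2()].
#' @return an object of class `metrics_report`.
#' @examples
#' m <- classification_metrics(confusion_from_counts(tp = 67, fn = 4,
#'                                                   fp = 2, tn = 77))
#' m$report
#' @export
classification_metrics <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix2"))
  if (cm$total == 0) stop("empty confusion matrix", call. = FALSE)
  mel <- .prf(cm$tp, cm$fp, cm$fn)
  ben <- .prf(cm$tn, cm$fn, cm$fp)   # benign as positive swaps error roles
  accuracy <- (cm$tp + cm$tn) / cm$total
  macro <- (mel + ben) / 2
  zero_division <- (cm$tp + cm$fp == 0) || (cm$tp + cm$fn == 0) ||
    (cm$tn + cm$fn == 0) || (cm$tn + cm$fp == 0)
  pct <- function(x) 100 * x
  unrounded <- list(
    melanoma = pct(mel), benign = pct(ben), macro = pct(macro),
    accuracy = pct(accuracy))
  report <- data.frame(
    class = c("Melanoma", "Benign", "Average"),
    accuracy = round_half_up(rep(unrounded$accuracy, 3)),
    precision = round_half_up(c(unrounded$melanoma["precision"],
                                unrounded$benign["precision"],
                                unrounded$macro["precision"])),
    recall = round_half_up(c(unrounded$melanoma["recall"],
                             unrounded$benign["recall"],
                             unrounded$macro["recall"])),
    f_score = round_half_up(c(unrounded$melanoma["f_score"],
                              unrounded$benign["f_score"],
                              unrounded$macro["f_score"])),
    row.names = NULL)
  structure(list(confusion = cm, unrounded = unrounded, report = report,
                 accuracy = round_half_up(unrounded$accuracy),
                 zero_division = zero_division),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat("Confusion (melanoma positive): tp =", x$confusion$tp,
      " fn =", x$confusion$fn, " fp =", x$confusion$fp,
      " tn =", x$confusion$tn, "\n")
  print(x$report, row.names = FALSE)
  invisible(x)
}

#' ROC curve points from scores
#'
#' Sweeps the decision threshold over the unique scores (classifying
#' `score >= threshold` as melanoma) and returns the (FPR, TPR) points,
#' anchored at (0,0) and (1,1), plus the trapezoidal area under the curve.
#'
#' @param truth vector of `"melanoma"` / `"benign"` truths (both present).
#' @param scores finite numeric scores, higher meaning more melanoma-like.
#' @return a list with `points` (data.frame `fpr`, `tpr`, `threshold`) and
#'   `auc`.
#' @export
roc_points <- function(truth, scores) {
  sw <- .threshold_sweep(truth, scores)
  fpr <- c(0, sw$fp / sw$n_neg, 1)
  tpr <- c(0, sw$tp / sw$n_pos, 1)
  thr <- c(Inf, sw$thresholds, -Inf)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  list(points = data.frame(fpr = fpr, tpr = tpr, threshold = thr), auc = auc)
}

#' Precision-recall curve points from scores
#'
#' Threshold sweep companion to [roc_points()]; the precision at recall 0
#' is taken from the highest (most conservative) threshold.
#'
#' @inheritParams roc_points
#' @return a list with `points` (data.frame `recall`, `precision`,
#'   `threshold`) and `auc` (trapezoidal area).
#' @export
pr_points <- function(truth, scores) {
  sw <- .threshold_sweep(truth, scores)
  precision <- ifelse(sw$tp + sw$fp == 0, 1, sw$tp / (sw$tp + sw$fp))
  recall <- sw$tp / sw$n_pos
  precision <- c(precision[1], precision)
  recall <- c(0, recall)
  thr <- c(Inf, sw$thresholds)
  auc <- sum(diff(recall) *
               (utils::head(precision, -1) + utils::tail(precision, -1)) / 2)
  list(points = data.frame(recall = recall, precision = precision,
                           threshold = thr), auc = auc)
}

.threshold_sweep <- function(truth, scores) {
  truth <- as.character(truth)
  if (!all(is.finite(scores))) stop("scores must be finite", call. = FALSE)
  stopifnot(length(truth) == length(scores))
  n_pos <- sum(truth == "melanoma")
  n_neg <- sum(truth == "benign")
  if (n_pos == 0L || n_neg == 0L) {
    stop("both classes must be present in `truth`", call. = FALSE)
  }
  thresholds <- sort(unique(scores), decreasing = TRUE)
  tp <- fp <- numeric(length(thresholds))
  for (k in seq_along(thresholds)) {
    called <- scores >= thresholds[k]
    tp[k] <- sum(called & truth == "melanoma")
    fp[k] <- sum(called & truth == "benign")
  }
  list(thresholds = thresholds, tp = tp, fp = fp, n_pos = n_pos, n_neg = n_neg)
}
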