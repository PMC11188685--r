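## One-label and macro evaluation: confusion metrics, ROC and PR curves with
## areas, and the shared-threshold macro curves used for the two-label task.

#' Precision/recall metrics from confusion counts
#'
#' `precision = TP/(TP+FP)`, `recall = TP/(TP+FN)`, `F1 = 2PR/(P+R)`,
#' `TNR = TN/(TN+FP) = 1 - FPR`. A ratio with zero denominator is reported
#' as 0 and flagged degenerate rather than propagating NaN into macro means.
#'
#' @param tp,fp,tn,fn Nonnegative integer counts; alternatively pass a list
#'   with these names as `tp`.
#' @return List with `precision`, `recall`, `f1`, `tnr`, `fpr`, and
#'   `degenerate` (character vector naming any zero-denominator metrics).
#' @export
prf_metrics <- function(tp, fp = NULL, tn = NULL, fn = NULL) {
  if (is.list(tp)) {
    fp <- tp$fp; tn <- tp$tn; fn <- tp$fn; tp <- tp$tp
  }
  degenerate <- character(0)
  safe <- function(num, den, name) {
    if (den == 0) {
      degenerate <<- c(degenerate, name)
      return(0)
    }
    num / den
  }
  precision <- safe(tp, tp + fp, "precision")
  recall <- safe(tp, tp + fn, "recall")
  f1 <- safe(2 * precision * recall, precision + recall, "f1")
  tnr <- safe(tn, tn + fp, "tnr")
  fpr <- if (tn + fp == 0) 0 else fp / (tn + fp)
  list(precision = precision, recall = recall, f1 = f1, tnr = tnr, fpr = fpr,
       degenerate = degenerate)
}

confusion_counts <- function(pred, truth) {
  pred <- as.logical(pred); truth <- as.logical(truth)
  list(tp = sum(pred & truth), fp = sum(pred & !truth),
       tn = sum(!pred & !truth), fn = sum(!pred & truth))
}

new_curve <- function(thresholds, x, y, area) {
  structure(list(thresholds = thresholds,
                 points = new_df(x = x, y = y), area = area),
            class = "curve_result")
}

#' @export
print.curve_result <- function(x, ...) {
  cat(sprintf("<curve_result: %d points, area %.4f>\n", nrow(x$points), x$area))
  invisible(x)
}

sweep_confusion <- function(scores, labels) {
  ## decreasing unique thresholds; prediction = score >= t; ties grouped
  th <- sort(unique(scores), decreasing = TRUE)
  npos <- sum(labels); nneg <- sum(!labels)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- labels[ord]
  ctp <- cumsum(y); cfp <- cumsum(!y)
  last <- cumsum(as.integer(table(factor(-s, levels = unique(-s)))))
  list(th = th, tp = ctp[last], fp = cfp[last], npos = npos, nneg = nneg)
}

#' ROC curve and area
#'
#' Threshold sweep over the unique scores (ties grouped); the curve plots
#' recall (TPR) against FPR and the area is the trapezoidal integral, which
#' equals the Mann-Whitney probability that a random positive outscores a
#' random negative (ties counting one half).
#'
#' @param scores Numeric scores (higher = more positive).
#' @param labels Logical/binary truth; both classes must be present.
#' @return A `curve_result` (`points$x` = FPR, `points$y` = recall).
#' @export
roc_auroc <- function(scores, labels) {
  labels <- as.logical(labels)
  if (length(scores) != length(labels)) err_contract("scores/labels length mismatch")
  if (!any(labels) || all(labels)) err_eval("ROC needs both classes present")
  sw <- sweep_confusion(scores, labels)
  fpr <- c(0, sw$fp / sw$nneg)
  tpr <- c(0, sw$tp / sw$npos)
  area <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  new_curve(sw$th, fpr, tpr, area)
}

#' Precision-recall curve and area
#'
#' Step-wise PR curve with no interpolation: sweeping thresholds from high
#' to low, each threshold group contributes `(recall gain) * precision`. The
#' curve anchors at the precision of the top-scored group.
#'
#' @inheritParams roc_auroc
#' @return A `curve_result` (`points$x` = recall, `points$y` = precision).
#' @export
pr_auprc <- function(scores, labels) {
  labels <- as.logical(labels)
  if (length(scores) != length(labels)) err_contract("scores/labels length mismatch")
  if (!any(labels)) err_eval("PR curve needs at least one positive")
  sw <- sweep_confusion(scores, labels)
  recall <- sw$tp / sw$npos
  precision <- sw$tp / (sw$tp + sw$fp)
  area <- sum(diff(c(0, recall)) * precision)
  new_curve(sw$th, recall, precision, area)
}

#' Macro (two-label) metric summary
#'
#' Each macro value is the arithmetic mean of the two one-label values.
#'
#' @param target,tf Metric lists from [prf_metrics()] for the target-gene
#'   and TF labels.
#' @return List of macro `precision`, `recall`, `f1`, `fpr`, `tnr`.
#' @export
macro_metrics <- function(target, tf) {
  avg <- function(k) (target[[k]] + tf[[k]]) / 2
  list(precision = avg("precision"), recall = avg("recall"), f1 = avg("f1"),
       fpr = avg("fpr"), tnr = avg("tnr"))
}

macro_confusion_at <- function(t, scores, labels) {
  confusion_counts(scores >= t, labels)
}

#' Macro ROC and PR curves over a shared threshold sweep
#'
#' Thresholds sweep the union of both labels' scores; at each threshold the
#' macro recall, FPR and precision are the means of the two labels' values.
#' The macro ROC area is the trapezoidal integral over (macro FPR, macro
#' recall); the macro PR area is the step integral over (macro recall, macro
#' precision). A label with no predicted positives at some threshold
#' contributes precision 1 there (the empty-prediction limit), keeping the
#' anchor at recall 0 well defined.
#'
#' @param scores_target,scores_tf Scores for the two labels.
#' @param labels_target,labels_tf Truth vectors for the two labels.
#' @return List with `roc` and `pr` `curve_result`s.
#' @export
macro_curves <- function(scores_target, scores_tf, labels_target, labels_tf) {
  labels_target <- as.logical(labels_target)
  labels_tf <- as.logical(labels_tf)
  if (!any(labels_target) || all(labels_target) ||
      !any(labels_tf) || all(labels_tf)) {
    err_eval("macro curves need both classes present for each label")
  }
  th <- sort(unique(c(scores_target, scores_tf)), decreasing = TRUE)
  one <- function(t, scores, labels) {
    cc <- confusion_counts(scores >= t, labels)
    c(recall = cc$tp / (cc$tp + cc$fn),
      fpr = cc$fp / (cc$fp + cc$tn),
      precision = if (cc$tp + cc$fp == 0) 1 else cc$tp / (cc$tp + cc$fp))
  }
  vals <- vapply(th, function(t) {
    (one(t, scores_target, labels_target) + one(t, scores_tf, labels_tf)) / 2
  }, numeric(3))
  recall <- vals["recall", ]; fpr <- vals["fpr", ]; precision <- vals["precision", ]
  rx <- c(0, fpr); ry <- c(0, recall)
  roc_area <- sum(diff(rx) * (utils::head(ry, -1) + utils::tail(ry, -1)) / 2)
  ## close the ROC at (1, 1): thresholds below the minimum score predict all
  roc_area <- roc_area + (1 - rx[length(rx)]) * (1 + ry[length(ry)]) / 2
  pr_area <- sum(diff(c(0, recall)) * precision)
  list(roc = new_curve(th, c(rx, 1), c(ry, 1), roc_area),
       pr = new_curve(th, recall, precision, pr_area))
}
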