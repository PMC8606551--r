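# Classifier performance metrics: accuracy / precision / sensitivity at a
# fixed threshold, threshold-weighted average precision, and trapezoidal
# ROC AUC.

#' Confusion counts at a threshold
#'
#' @param scores positive-class scores in \[0, 1\].
#' @param labels true 0/1 labels.
#' @param threshold decision threshold (score >= threshold is positive).
#' @return Named integer vector `TP`, `FP`, `FN`, `TN`.
#' @export
confusion_counts <- function(scores, labels, threshold = 0.5) {
  stopifnot(length(scores) == length(labels))
  pred <- as.integer(scores >= threshold)
  c(TP = sum(pred == 1 & labels == 1),
    FP = sum(pred == 1 & labels == 0),
    FN = sum(pred == 0 & labels == 1),
    TN = sum(pred == 0 & labels == 0))
}

#' ROC curve points
#'
#' @param scores,labels as in [confusion_counts()].
#' @return Data frame `threshold`, `fpr`, `tpr`, ordered from (0,0) to
#'   (1,1).
#' @export
roc_curve <- function(scores, labels) {
  np <- sum(labels == 1); nn <- sum(labels == 0)
  if (np == 0 || nn == 0) stop("ROC needs both classes")
  th <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(th, function(t) sum(scores >= t & labels == 1) / np,
                numeric(1))
  fpr <- vapply(th, function(t) sum(scores >= t & labels == 0) / nn,
                numeric(1))
  data.frame(threshold = c(Inf, th), fpr = c(0, fpr), tpr = c(0, tpr))
}

#' Performance metrics for one score vector
#'
#' Accuracy, precision and sensitivity at the threshold; average precision
#' as the recall-step-weighted mean of precision over score thresholds;
#' AUC by trapezoidal integration of the ROC curve. With one-class labels,
#' AUC and AP are reported as `NA`.
#'
#' @param scores,labels,threshold as in [confusion_counts()].
#' @return List `metrics` (named numeric: `accuracy`, `precision`,
#'   `sensitivity`, `ap`, `auc`) and `confusion`.
#' @export
compute_metrics <- function(scores, labels, threshold = 0.5) {
  cc <- confusion_counts(scores, labels, threshold)
  acc <- (cc["TP"] + cc["TN"]) / sum(cc)
  prec <- if (cc["TP"] + cc["FP"] > 0) cc["TP"] / (cc["TP"] + cc["FP"])
          else NA_real_
  sens <- if (cc["TP"] + cc["FN"] > 0) cc["TP"] / (cc["TP"] + cc["FN"])
          else NA_real_
  both <- length(unique(labels)) == 2
  auc <- ap <- NA_real_
  if (both) {
    rc <- roc_curve(scores, labels)
    auc <- sum(diff(rc$fpr) * (head(rc$tpr, -1) + tail(rc$tpr, -1)) / 2)
    # average precision: sum over descending thresholds of
    # (recall_n - recall_{n-1}) * precision_n
    th <- sort(unique(scores), decreasing = TRUE)
    np <- sum(labels == 1)
    rec_prev <- 0
    ap <- 0
    for (t in th) {
      tp <- sum(scores >= t & labels == 1)
      fp <- sum(scores >= t & labels == 0)
      rec <- tp / np
      pr <- tp / (tp + fp)
      ap <- ap + (rec - rec_prev) * pr
      rec_prev <- rec
    }
  }
  list(metrics = c(accuracy = unname(acc), precision = unname(prec),
                   sensitivity = unname(sens), ap = unname(ap),
                   auc = unname(auc)),
       confusion = cc)
}
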