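#' Classification metrics from confusion counts
#'
#' Computes the full metric suite from the four confusion-matrix counts:
#' sensitivity `SN = TP/(TP+FN)`, specificity `SP = TN/(TN+FP)`, accuracy
#' `(TP+TN)/total`, precision `p = TP/(TP+FP)`, `F1 = 2*SN*p/(SN+p)` and
#' the Matthews correlation coefficient
#' `MCC = (TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`.
#' Any metric with a zero denominator is reported as 0, so degenerate
#' classifiers (e.g. everything predicted negative) still yield a full
#' report.
#'
#' @param tp,tn,fp,fn Nonnegative confusion counts.
#' @return Named numeric vector: `tp`, `tn`, `fp`, `fn`, `acc`, `sn`,
#'   `sp`, `precision`, `f1`, `mcc`.
#' @export
metrics_from_counts <- function(tp, tn, fp, fn) {
  stopifnot(tp >= 0, tn >= 0, fp >= 0, fn >= 0)
  sn <- div0(tp, tp + fn)
  sp <- div0(tn, tn + fp)
  prec <- div0(tp, tp + fp)
  # product of the four marginals can overflow integer range; use doubles
  denom <- sqrt(prod(c(tp + fp, tp + fn, tn + fp, tn + fn)))
  mcc <- if (denom == 0) 0 else (tp * tn - fp * fn) / denom
  c(tp = tp, tn = tn, fp = fp, fn = fn,
    acc = div0(tp + tn, tp + tn + fp + fn),
    sn = sn, sp = sp, precision = prec,
    f1 = div0(2 * sn * prec, sn + prec),
    mcc = mcc)
}

#' Trapezoidal area under the ROC curve
#'
#' Sweeps the decision threshold over the observed scores, computes the
#' (FPR, TPR) operating points, and accumulates the trapezoidal sum
#' `sum(TPR_i * dFPR + dTPR * dFPR / 2)` between consecutive points
#' (anchored at (0,0) and (1,1)). For binary 0/1 scores the curve
#' collapses to a single operating point and the area reduces exactly to
#' `(SN + SP)/2`.
#'
#' @param scores Numeric prediction scores (higher = more positive).
#' @param labels Binary labels (0/1) aligned to `scores`.
#' @return The area under the ROC curve in \[0, 1\].
#' @export
auc_trapezoid <- function(scores, labels) {
  labels <- as.integer(labels)
  if (length(scores) != length(labels))
    stop("scores and labels must have the same length")
  pts <- roc_points(scores, labels)
  sum(diff(pts$fpr) * (head(pts$tpr, -1) + diff(pts$tpr) / 2))
}

roc_points <- function(scores, labels) {
  ord <- order(scores, decreasing = TRUE)
  labels <- labels[ord]; scores <- scores[ord]
  n_pos <- sum(labels == 1L); n_neg <- sum(labels == 0L)
  if (n_pos == 0L || n_neg == 0L) stop("both classes must be present")
  # one operating point per distinct score value
  last <- cumsum(rep(1L, length(scores)))[!duplicated(scores, fromLast = TRUE)]
  tp <- cumsum(labels == 1L)[last]
  fp <- cumsum(labels == 0L)[last]
  list(fpr = c(0, fp / n_neg, 1), tpr = c(0, tp / n_pos, 1))
}

#' Area under the precision-recall curve (average precision)
#'
#' Step-sum (average-precision) form: `sum((R_i - R_{i-1}) * P_i)` over
#' threshold-swept operating points ordered by decreasing score.
#'
#' @inheritParams auc_trapezoid
#' @return The area under the precision-recall curve in \[0, 1\].
#' @export
auprc <- function(scores, labels) {
  labels <- as.integer(labels)
  if (length(scores) != length(labels))
    stop("scores and labels must have the same length")
  ord <- order(scores, decreasing = TRUE)
  labels <- labels[ord]; scores <- scores[ord]
  n_pos <- sum(labels == 1L)
  if (n_pos == 0L) stop("no positive labels")
  last <- cumsum(rep(1L, length(scores)))[!duplicated(scores, fromLast = TRUE)]
  tp <- cumsum(labels == 1L)[last]
  fp <- cumsum(labels == 0L)[last]
  recall <- tp / n_pos
  prec <- tp / (tp + fp)
  sum(diff(c(0, recall)) * prec)
}

#' Evaluate prediction scores against labels
#'
#' Thresholds `scores` at `threshold` to form the confusion matrix, then
#' derives the count-based metric suite plus threshold-free AUC
#' ([auc_trapezoid()]) and AUPRC ([auprc()]).
#'
#' @param scores Numeric scores in \[0, 1\] (probability of the positive
#'   class).
#' @param labels Binary labels (0/1).
#' @param threshold Decision threshold (label 1 iff score >= threshold).
#' @return An object of class `eval_report`: the [metrics_from_counts()]
#'   vector extended with `auc` and `auprc`.
#' @export
evaluate_scores <- function(scores, labels, threshold = 0.5) {
  labels <- as.integer(labels)
  if (length(scores) != length(labels))
    stop("scores and labels must have the same length")
  pred <- as.integer(scores >= threshold)
  m <- metrics_from_counts(tp = sum(pred == 1L & labels == 1L),
                           tn = sum(pred == 0L & labels == 0L),
                           fp = sum(pred == 1L & labels == 0L),
                           fn = sum(pred == 0L & labels == 1L))
  out <- c(m, auc = auc_trapezoid(scores, labels), auprc = auprc(scores, labels))
  class(out) <- "eval_report"
  out
}

#' @export
print.eval_report <- function(x, ...) {
  cat("Evaluation report\n")
  cat(sprintf("  TP %d  TN %d  FP %d  FN %d\n",
              as.integer(x["tp"]), as.integer(x["tn"]),
              as.integer(x["fp"]), as.integer(x["fn"])))
  for (nm in c("acc", "sp", "sn", "mcc", "precision", "f1", "auc", "auprc"))
    cat(sprintf("  %-9s %.6f\n", nm, x[nm]))
  invisible(x)
}
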