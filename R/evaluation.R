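# Confusion-matrix metrics, ROC/AUC and AUPRC for imbalanced binary
# classification. Predictions use the rule score >= threshold (ties
# predicted positive). The specificity denominator is TN + FP, the
# universal definition.

checkScored <- function(labels, scores) {
  if (length(labels) != length(scores))
    stop("labels and scores must have equal length")
  if (length(labels) < 1L) stop("empty input")
  if (!all(labels %in% c(0, 1))) stop("labels must be 0 or 1")
  invisible(NULL)
}

#' Confusion matrix at a decision threshold
#'
#' Tallies predictions (score >= threshold is positive) against true binary
#' labels.
#'
#' @param labels True binary labels.
#' @param scores Real scores in [0, 1].
#' @param threshold Decision threshold in [0, 1], default 0.5.
#' @return Named integer vector with elements TP, FP, TN, FN.
#' @export
#' @examples
#' confusionAtThreshold(c(1, 0), c(0.9, 0.1))
confusionAtThreshold <- function(labels, scores, threshold = 0.5) {
  checkScored(labels, scores)
  stopifnot(threshold >= 0, threshold <= 1)
  pred <- as.integer(scores >= threshold)
  c(TP = sum(pred == 1L & labels == 1), FP = sum(pred == 1L & labels == 0),
    TN = sum(pred == 0L & labels == 0), FN = sum(pred == 0L & labels == 1))
}

#' Accuracy, sensitivity and specificity
#'
#' accuracy = (TP + TN) / (TP + TN + FP + FN), sensitivity = TP / (TP + FN),
#' specificity = TN / (TN + FP). A metric whose denominator is zero is
#' reported as NaN.
#'
#' @param cm Named count vector with TP, FP, TN, FN (from
#'   [confusionAtThreshold()]).
#' @return Named numeric vector (accuracy, sensitivity, specificity).
#' @export
basicMetrics <- function(cm) {
  tp <- cm[["TP"]]; fp <- cm[["FP"]]; tn <- cm[["TN"]]; fn <- cm[["FN"]]
  n <- tp + fp + tn + fn
  if (n < 1) stop("confusion matrix is empty")
  div <- function(a, b) if (b > 0) a / b else NaN
  c(accuracy = (tp + tn) / n,
    sensitivity = div(tp, tp + fn),
    specificity = div(tn, tn + fp))
}

#' Matthews correlation coefficient
#'
#' MCC = (TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN)); returns 0 by
#' convention when any denominator factor is zero.
#'
#' @inheritParams basicMetrics
#' @return Numeric in [-1, 1].
#' @export
mccScore <- function(cm) {
  tp <- cm[["TP"]]; fp <- cm[["FP"]]; tn <- cm[["TN"]]; fn <- cm[["FN"]]
  fac <- c(tp + fp, tp + fn, tn + fp, tn + fn)
  if (any(fac == 0)) return(0)
  (tp * tn - fp * fn) / sqrt(prod(fac))
}

#' ROC curve
#'
#' One (FPR, TPR) point per distinct score threshold (prediction rule score
#' >= threshold, so tied scores move together) plus the (0, 0) endpoint;
#' both coordinates are non-decreasing and the curve ends at (1, 1).
#'
#' @param labels True binary labels; both classes must be present.
#' @param scores Real scores.
#' @return data.frame with columns threshold, fpr, tpr.
#' @export
rocCurve <- function(labels, scores) {
  checkScored(labels, scores)
  P <- sum(labels == 1)
  N <- sum(labels == 0)
  if (P == 0 || N == 0) stop("ROC requires both classes")
  ord <- order(scores, decreasing = TRUE)
  y <- labels[ord]
  s <- scores[ord]
  tps <- cumsum(y == 1)
  fps <- cumsum(y == 0)
  last <- which(!duplicated(s, fromLast = TRUE))  # last index of each tie group
  data.frame(threshold = c(Inf, s[last]),
             fpr = c(0, fps[last] / N),
             tpr = c(0, tps[last] / P))
}

#' Area under the ROC curve
#'
#' Trapezoidal area under [rocCurve()]. Internally also computed as the
#' Mann-Whitney statistic (ties counted one half) and the two are asserted
#' to agree within 1e-9.
#'
#' @inheritParams rocCurve
#' @return Numeric in [0, 1].
#' @export
#' @examples
#' aucScore(c(1, 1, 0, 0), c(0.8, 0.4, 0.6, 0.2))  # 0.75
aucScore <- function(labels, scores) {
  roc <- rocCurve(labels, scores)
  trap <- sum(diff(roc$fpr) * (roc$tpr[-1] + roc$tpr[-nrow(roc)]) / 2)
  P <- sum(labels == 1)
  N <- sum(labels == 0)
  r <- rank(scores)  # average ranks give half credit to ties
  mw <- (sum(r[labels == 1]) - P * (P + 1) / 2) / (P * N)
  stopifnot(abs(trap - mw) < 1e-9)
  trap
}

#' Area under the precision-recall curve
#'
#' Step-wise average precision: sum over descending-score threshold groups
#' of (R_k - R_(k-1)) * P_k. The step rule is used rather than trapezoids,
#' whose linear precision interpolation is optimistic.
#'
#' @param labels True binary labels; at least one positive required.
#' @param scores Real scores.
#' @return Numeric in (0, 1].
#' @export
auprcScore <- function(labels, scores) {
  checkScored(labels, scores)
  P <- sum(labels == 1)
  if (P == 0) stop("AUPRC requires at least one positive")
  ord <- order(scores, decreasing = TRUE)
  y <- labels[ord]
  s <- scores[ord]
  tps <- cumsum(y == 1)
  k <- seq_along(y)
  last <- which(!duplicated(s, fromLast = TRUE))
  recall <- tps[last] / P
  precision <- tps[last] / k[last]
  sum(diff(c(0, recall)) * precision)
}

#' Evaluate a model on a labeled dataset
#'
#' Predicts probabilities and reports the six headline metrics at the given
#' threshold.
#'
#' @param weights A \linkS4class{ModelWeights}.
#' @param dataset A labeled \linkS4class{PSSMSet}.
#' @param threshold Decision threshold, default 0.5.
#' @return List with \code{metrics} (sensitivity, specificity, accuracy,
#'   auc, mcc, auprc), \code{roc} (data.frame) and \code{probabilities}.
#' @export
evaluateModel <- function(weights, dataset, threshold = 0.5) {
  y <- checkLabeled(dataset)
  p <- predictProbs(weights, dataset)
  cm <- confusionAtThreshold(y, p, threshold)
  bm <- basicMetrics(cm)
  list(metrics = list(sensitivity = bm[["sensitivity"]],
                      specificity = bm[["specificity"]],
                      accuracy = bm[["accuracy"]],
                      auc = aucScore(y, p),
                      mcc = mccScore(cm),
                      auprc = auprcScore(y, p)),
       confusion = cm, roc = rocCurve(y, p), probabilities = p)
}
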