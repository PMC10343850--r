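#' Threshold-based classification metrics
#'
#' Hard labels are `score >= threshold`. Reports the confusion counts and
#' accuracy, precision, sensitivity (recall), specificity, Matthews
#' correlation coefficient and F1. MCC is defined as 0 whenever its
#' denominator vanishes (e.g. all predictions in one class).
#'
#' @param y binary labels (0/1).
#' @param scores numeric scores, same length as `y`.
#' @param threshold decision threshold (default 0.5).
#' @return A list of class `metrics_report` with `TP`, `TN`, `FP`, `FN`,
#'   `acc`, `pre`, `sen`, `spe`, `mcc`, `f1`, `auc`, `aupr`, `threshold`.
#'   AUC/AUPR are included when both classes are present (NA otherwise is
#'   impossible here since they error; they are computed via [roc_auc()] and
#'   [pr_auc()]).
#' @export
confusion_metrics <- function(y, scores, threshold = 0.5) {
  if (!length(y)) stopf("empty input")
  if (length(y) != length(scores)) stopf("y and scores lengths differ")
  pred <- as.numeric(scores >= threshold)
  tp <- sum(pred == 1 & y == 1); tn <- sum(pred == 0 & y == 0)
  fp <- sum(pred == 1 & y == 0); fn <- sum(pred == 0 & y == 1)
  safe_div <- function(num, den) if (den == 0) 0 else num / den
  acc <- (tp + tn) / length(y)
  pre <- safe_div(tp, tp + fp)
  sen <- safe_div(tp, tp + fn)
  spe <- safe_div(tn, tn + fp)
  mcc_den <- sqrt(prod(c(tp + fp, tp + fn, tn + fp, tn + fn)))
  mcc <- if (mcc_den == 0) 0 else (tp * tn - fp * fn) / mcc_den
  f1 <- safe_div(2 * tp, 2 * tp + fp + fn)
  both <- length(unique(y)) == 2
  structure(list(TP = tp, TN = tn, FP = fp, FN = fn,
                 acc = acc, pre = pre, sen = sen, spe = spe,
                 mcc = mcc, f1 = f1,
                 auc = if (both) roc_auc(y, scores) else NA_real_,
                 aupr = if (both) pr_auc(y, scores) else NA_real_,
                 threshold = threshold),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("acc %.4f  pre %.4f  sen %.4f  spe %.4f  mcc %.4f  f1 %.4f  auc %.4f  aupr %.4f\n",
              x$acc, x$pre, x$sen, x$spe, x$mcc, x$f1, x$auc, x$aupr))
  invisible(x)
}

#' Area under the ROC curve
#'
#' Tie-aware rank (Mann-Whitney) statistic: ties between a positive and a
#' negative score count one half. Equivalent to trapezoidal integration of
#' the ROC curve over all thresholds.
#'
#' @param y binary labels, both classes present.
#' @param scores numeric scores.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(y, scores) {
  y <- as.numeric(y)
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) stopf("both classes required for AUC")
  r <- rank(scores, ties.method = "average")
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Area under the precision-recall curve
#'
#' Step-wise summation over descending score thresholds (average precision),
#' with tied scores processed as one group.
#'
#' @param y binary labels, both classes present.
#' @param scores numeric scores.
#' @return AUPR in `(0, 1]`.
#' @export
pr_auc <- function(y, scores) {
  y <- as.numeric(y)
  n1 <- sum(y == 1)
  if (n1 == 0 || n1 == length(y)) stopf("both classes required for AUPR")
  ord <- order(scores, decreasing = TRUE)
  ys <- y[ord]; ss <- scores[ord]
  grp_last <- cumsum(rle(ss)$lengths)   # index of last element of each tie group
  tp <- cumsum(ys)[grp_last]
  n_pred <- grp_last
  precision <- tp / n_pred
  recall <- tp / n1
  sum(diff(c(0, recall)) * precision)
}

#' ROC and precision-recall curve points
#'
#' One point per distinct score threshold (descending), for export and
#' plotting by external tools.
#'
#' @param y binary labels.
#' @param scores numeric scores.
#' @return A data.frame: `threshold`, `fpr`, `tpr` for [roc_points()];
#'   `threshold`, `recall`, `precision` for [pr_points()].
#' @export
roc_points <- function(y, scores) {
  y <- as.numeric(y)
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  ord <- order(scores, decreasing = TRUE)
  ys <- y[ord]; ss <- scores[ord]
  grp_last <- cumsum(rle(ss)$lengths)
  tp <- cumsum(ys)[grp_last]
  fp <- grp_last - tp
  data.frame(threshold = c(Inf, ss[grp_last]),
             fpr = c(0, fp / n0), tpr = c(0, tp / n1))
}

#' @rdname roc_points
#' @export
pr_points <- function(y, scores) {
  y <- as.numeric(y)
  n1 <- sum(y == 1)
  ord <- order(scores, decreasing = TRUE)
  ys <- y[ord]; ss <- scores[ord]
  grp_last <- cumsum(rle(ss)$lengths)
  tp <- cumsum(ys)[grp_last]
  data.frame(threshold = ss[grp_last], recall = tp / n1,
             precision = tp / grp_last)
}
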