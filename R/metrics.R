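#' Confusion counts
#'
#' Tallies true/false positives and negatives for binary predictions
#' against binary labels.
#'
#' @param predictions binary vector (0/1), or positive-class
#'   probabilities which are thresholded at 0.5.
#' @param labels binary vector of the same length.
#' @return named list with `tp`, `tn`, `fp`, `fn`.
#' @export
confusion_counts <- function(predictions, labels) {
  if (length(predictions) != length(labels))
    stop("predictions and labels must have equal length")
  if (!all(labels %in% c(0, 1))) stop("labels must be exactly 0 or 1")
  pred <- as.integer(predictions >= 0.5)
  list(tp = sum(pred == 1L & labels == 1),
       tn = sum(pred == 0L & labels == 0),
       fp = sum(pred == 1L & labels == 0),
       fn = sum(pred == 0L & labels == 1))
}

#' Derived classification metrics
#'
#' Accuracy, sensitivity, specificity and F1 from confusion counts:
#' accuracy `(TP+TN)/(TP+FP+TN+FN)`, sensitivity `TP/(TP+FN)`,
#' specificity `TN/(TN+FP)`, F1 `2TP/(2TP+FN+FP)`. A zero denominator
#' yields 0 with a warning, so sweep tables stay total.
#'
#' @param counts list from [confusion_counts()].
#' @return named list of the four metrics, each in `[0, 1]`.
#' @export
compute_metrics <- function(counts) {
  tp <- counts$tp; tn <- counts$tn; fp <- counts$fp; fn <- counts$fn
  total <- tp + tn + fp + fn
  if (total <= 0) stop("no evaluated records")
  safe_div <- function(num, den, what) {
    if (den == 0) {
      warning(what, " undefined (zero denominator); reporting 0",
              call. = FALSE)
      0
    } else num / den
  }
  list(accuracy = (tp + tn) / total,
       sensitivity = safe_div(tp, tp + fn, "sensitivity"),
       specificity = safe_div(tn, tn + fp, "specificity"),
       f1 = safe_div(2 * tp, 2 * tp + fn + fp, "F1"))
}

#' Area under the ROC curve
#'
#' Computed as the Mann-Whitney statistic: the proportion of
#' positive/negative pairs the score orders correctly, ties counted as
#' one half, evaluated via midranks.
#'
#' @param scores positive-class probabilities (or any monotone score).
#' @param labels binary labels; both classes must be present.
#' @return AUC in `[0, 1]`.
#' @export
auc_score <- function(scores, labels) {
  if (length(scores) != length(labels))
    stop("scores and labels must have equal length")
  if (!all(labels %in% c(0, 1))) stop("labels must be exactly 0 or 1")
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0)
    stop("AUC undefined: both classes must be present")
  r <- rank(scores)                       # midranks handle ties
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}
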