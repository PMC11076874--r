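# Five-metric evaluation suite: accuracy, recall, precision, F1 from the
# confusion counts, plus AUC via the Mann-Whitney rank statistic.

#' Confusion counts
#'
#' @param labels true 0/1 labels (1 = spindle).
#' @param predicted predicted 0/1 labels.
#' @return named integer vector with `TP`, `FP`, `TN`, `FN`.
#' @export
confusion_counts <- function(labels, predicted) {
  labels <- as.integer(labels)
  predicted <- as.integer(predicted)
  if (length(labels) != length(predicted)) {
    stopf("labels and predictions differ in length")
  }
  c(TP = sum(labels == 1L & predicted == 1L),
    FP = sum(labels == 0L & predicted == 1L),
    TN = sum(labels == 0L & predicted == 0L),
    FN = sum(labels == 1L & predicted == 0L))
}

# AUC as the Mann-Whitney rank statistic: the probability that a random
# positive outscores a random negative, ties counted 1/2. Midranks give
# exactly the tie-1/2 convention.
auc_rank <- function(labels, scores) {
  n1 <- sum(labels == 1L)
  n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) {
    stopf("AUC needs at least one positive and one negative")
  }
  r <- rank(scores)
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Compute the evaluation metrics
#'
#' Accuracy = (TP+TN)/(TP+FP+TN+FN); recall = TP/(TP+FN) (spindle class);
#' precision = TP/(TP+FP); F1 = 2PR/(P+R), defined as 0 when P+R = 0;
#' AUC is the pairwise ranking probability with ties counted 1/2.
#' Predicted labels default to thresholding the spindle-class score at 0.5
#' (equivalently, softmax argmax).
#'
#' @param labels true 0/1 labels.
#' @param scores spindle-class probabilities (used for AUC and, when
#'   `predicted` is missing, for thresholding).
#' @param predicted optional predicted 0/1 labels.
#' @return named numeric vector: `accuracy`, `recall`, `f1`, `precision`,
#'   `auc`.
#' @examples
#' compute_metrics(c(1, 1, 0, 0), scores = c(0.9, 0.8, 0.4, 0.3))
#' @export
compute_metrics <- function(labels, scores, predicted = NULL) {
  labels <- as.integer(labels)
  if (!all(labels %in% c(0L, 1L))) stopf("labels must be 0/1")
  if (is.null(predicted)) predicted <- as.integer(scores >= 0.5)
  cc <- confusion_counts(labels, predicted)
  tp <- cc[["TP"]]; fp <- cc[["FP"]]; tn <- cc[["TN"]]; fn <- cc[["FN"]]
  if (tp + fn == 0L) stopf("recall undefined: no positive labels")
  accuracy <- (tp + tn) / (tp + fp + tn + fn)
  recall <- tp / (tp + fn)
  precision <- if (tp + fp == 0L) 0 else tp / (tp + fp)
  f1 <- if (precision + recall == 0) 0 else {
    2 * precision * recall / (precision + recall)
  }
  c(accuracy = accuracy, recall = recall, f1 = f1, precision = precision,
    auc = auc_rank(labels, scores))
}
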