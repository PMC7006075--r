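#' Area under the ROC curve
#'
#' Computed via the Mann-Whitney U statistic: the fraction of
#' (positive, negative) pairs in which the positive scores higher, with
#' ties counted one half. This equals the trapezoidal area under the ROC
#' curve traced over all score thresholds.
#'
#' @param scores numeric prediction scores.
#' @param labels binary labels (0/1 or logical), same length as `scores`.
#' @return AUROC in \[0, 1\].
#' @export
auroc <- function(scores, labels) {
  labels <- check_metric_inputs(scores, labels)
  n_pos <- sum(labels == 1)
  n_neg <- sum(labels == 0)
  if (n_pos == 0) stop("labels contain no positives; AUROC undefined")
  if (n_neg == 0) stop("labels contain no negatives; AUROC undefined")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Area under the precision-recall curve (average precision)
#'
#' Uses the step-wise average-precision formulation: with thresholds at the
#' distinct score values in decreasing order, AUPR is the sum over
#' thresholds of precision times the recall increment. Tied scores are
#' grouped and enter as a single step, and no linear interpolation in PR
#' space is performed (interpolating tools may report slightly larger
#' values).
#'
#' @inheritParams auroc
#' @return AUPR in (0, 1\].
#' @export
aupr <- function(scores, labels) {
  labels <- check_metric_inputs(scores, labels)
  n_pos <- sum(labels == 1)
  if (n_pos == 0) stop("labels contain no positives; AUPR undefined")
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]
  y <- labels[o]
  # group tied scores: cumulative counts at the end of each tie block
  last_of_block <- c(s[-length(s)] != s[-1], TRUE)
  tp <- cumsum(y)[last_of_block]
  n_pred <- seq_along(s)[last_of_block]
  precision <- tp / n_pred
  recall <- tp / n_pos
  sum(precision * diff(c(0, recall)))
}

check_metric_inputs <- function(scores, labels) {
  if (length(scores) != length(labels)) {
    stop("scores and labels differ in length")
  }
  labels <- as.numeric(labels)
  if (!all(labels %in% c(0, 1))) stop("labels must be binary")
  if (anyNA(scores) || anyNA(labels)) stop("missing values in metric inputs")
  labels
}
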