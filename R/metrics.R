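#' Area under the ROC curve
#'
#' The probability that a uniformly chosen positive outranks a uniformly
#' chosen negative, with ties counted as one half — the Mann-Whitney
#' rank statistic, computed from mid-ranks. Equals exhaustive pairwise
#' concordance.
#'
#' @param scores Numeric scores (higher = more positive).
#' @param labels Binary labels (0/1 or logical), both classes present.
#' @return AUROC in `[0, 1]`.
#' @examples
#' auroc(c(0.9, 0.6, 0.4, 0.1), c(1, 0, 1, 0)) # 0.75
#' @export
auroc <- function(scores, labels) {
  labels <- as.integer(labels)
  stopifnot(length(scores) == length(labels), all(labels %in% c(0L, 1L)))
  n_pos <- sum(labels == 1L)
  n_neg <- sum(labels == 0L)
  if (n_pos == 0L || n_neg == 0L) stop("both classes must be present for AUROC")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1L]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Area under the precision-recall curve (average precision)
#'
#' Step-wise average precision over the score-sorted list (descending;
#' ties broken by stable original order): the mean, over positives, of
#' the precision at the position where each positive is retrieved.
#'
#' @inheritParams auroc
#' @return AUPRC in `(0, 1]`; requires at least one positive.
#' @export
auprc <- function(scores, labels) {
  labels <- as.integer(labels)
  stopifnot(length(scores) == length(labels), all(labels %in% c(0L, 1L)))
  if (sum(labels == 1L) == 0L) stop("at least one positive is required for AUPRC")
  ord <- order(-scores)            # stable: ties keep original order
  y <- labels[ord]
  tp <- cumsum(y)
  precision <- tp / seq_along(y)
  sum(precision[y == 1L]) / sum(y)
}
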