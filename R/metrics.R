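#' ROC-AUC by the rank (Mann-Whitney) formula
#'
#' Tied scores receive average ranks, so a constant scorer gets 0.5.
#' Returns `NA` when either class is absent.
#'
#' @param scores numeric prediction scores.
#' @param truth binary 0/1 (or logical) ground truth.
#' @return AUC in `[0, 1]`, or `NA_real_` if undefined.
#' @export
roc_auc <- function(scores, truth) {
  truth <- as.integer(as.logical(truth))
  n1 <- sum(truth == 1L)
  n0 <- sum(truth == 0L)
  if (n1 == 0L || n0 == 0L) return(NA_real_)
  r <- rank(scores, ties.method = "average")
  (sum(r[truth == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Precision-recall AUC (average precision)
#'
#' Step-interpolated average precision: sum over descending score
#' thresholds of (recall increment) x (precision at threshold), with tied
#' scores handled as a single threshold block. Returns `NA` when there are
#' no positives.
#'
#' @param scores numeric prediction scores.
#' @param truth binary 0/1 (or logical) ground truth.
#' @return average precision in `[0, 1]`, or `NA_real_` if undefined.
#' @export
pr_auc <- function(scores, truth) {
  truth <- as.integer(as.logical(truth))
  n1 <- sum(truth == 1L)
  if (n1 == 0L) return(NA_real_)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  y <- truth[ord]
  tp <- cumsum(y)
  fp <- cumsum(1L - y)
  # keep only the last index of each tied-score block
  last <- c(s[-1] != s[-length(s)], TRUE)
  tp <- tp[last]
  fp <- fp[last]
  precision <- tp / (tp + fp)
  recall <- tp / n1
  sum(diff(c(0, recall)) * precision)
}
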