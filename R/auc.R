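#' Rank-based AUC
#'
#' The area under the ROC curve as the probability that a randomly chosen
#' positive is scored above a randomly chosen negative, with half credit for
#' ties (Mann-Whitney formulation).
#'
#' @param scores numeric classifier scores (higher = more positive).
#' @param labels logical or 0/1 vector of true classes.
#' @return AUC in \[0, 1\].
#' @export
auc_rank <- function(scores, labels) {
  labels <- as.logical(labels)
  stop_if_not(length(scores) == length(labels), "scores/labels length mismatch")
  np <- sum(labels); nn <- sum(!labels)
  stop_if_not(np > 0 && nn > 0, "need both positive and negative labels")
  r <- rank(scores)  # midranks handle ties with half credit
  (sum(r[labels]) - np * (np + 1) / 2) / (np * nn)
}

#' ROC curve by threshold sweep
#'
#' Sweeps every distinct score as a decision threshold (predict positive when
#' `score >= t`) and returns the (fpr, tpr) points, including the (0,0) and
#' (1,1) endpoints, ordered by increasing false-positive rate.
#'
#' @inheritParams auc_rank
#' @return data.frame with `threshold`, `fpr`, `tpr`.
#' @export
roc_points <- function(scores, labels) {
  labels <- as.logical(labels)
  np <- sum(labels); nn <- sum(!labels)
  stop_if_not(np > 0 && nn > 0, "need both positive and negative labels")
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; y <- labels[o]
  grp <- cumsum(c(TRUE, diff(s) != 0))
  tp <- cumsum(y); fp <- cumsum(!y)
  last <- !duplicated(grp, fromLast = TRUE)
  data.frame(threshold = c(Inf, s[last]),
             fpr = c(0, fp[last] / nn),
             tpr = c(0, tp[last] / np))
}

#' Trapezoidal area under an ROC curve
#'
#' @param roc data.frame from [roc_points()].
#' @return area in \[0, 1\].
#' @export
auc_trapezoid <- function(roc) {
  stop_if_not(all(c("fpr", "tpr") %in% names(roc)), "not an ROC data.frame")
  o <- order(roc$fpr, roc$tpr)
  x <- roc$fpr[o]; y <- roc$tpr[o]
  sum(diff(x) * (y[-1] + y[-length(y)]) / 2)
}
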