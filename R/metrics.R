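#' Area under the precision-recall curve (average precision)
#'
#' Average-precision summation: precision evaluated at each recall step, with
#' tied scores processed as a single threshold. No trapezoidal interpolation.
#' The no-skill baseline of this metric equals the positive prevalence.
#'
#' @param scores numeric prediction scores.
#' @param labels binary labels (0/1, logical, or `"positive"`/`"negative"`).
#' @return AUPRC in `[0, 1]`.
#' @export
auprc <- function(scores, labels) {
  y <- as_binary_labels(labels)
  if (length(scores) != length(y)) stopf("scores/labels length mismatch")
  if (sum(y) == 0 || sum(y) == length(y))
    stopf("need at least one positive and one negative label")
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]
  y <- y[o]
  # group tied scores into single thresholds
  grp <- cumsum(!duplicated(s))
  tp_g <- tapply(y, grp, sum)
  n_g <- tapply(rep(1L, length(y)), grp, sum)
  tp <- cumsum(tp_g)
  nn <- cumsum(n_g)
  prec <- tp / nn
  recall <- tp / sum(y)
  drecall <- diff(c(0, recall))
  sum(prec * drecall)
}

#' Area under the ROC curve
#'
#' The Mann-Whitney rank statistic: the probability that a random positive
#' scores above a random negative, counting ties as one half.
#'
#' @inheritParams auprc
#' @return AUROC in `[0, 1]`.
#' @export
auroc <- function(scores, labels) {
  y <- as_binary_labels(labels)
  if (length(scores) != length(y)) stopf("scores/labels length mismatch")
  n1 <- sum(y)
  n0 <- length(y) - n1
  if (n1 == 0 || n0 == 0)
    stopf("need at least one positive and one negative label")
  r <- rank(scores, ties.method = "average")
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

as_binary_labels <- function(labels) {
  if (is.character(labels) || is.factor(labels)) {
    labels <- as.character(labels)
    if (!all(labels %in% c("positive", "negative")))
      stopf("character labels must be 'positive'/'negative'")
    return(as.integer(labels == "positive"))
  }
  y <- as.integer(labels)
  if (!all(y %in% c(0L, 1L))) stopf("labels must be binary")
  y
}

#' Adjusted Rand index between two partitions
#'
#' Permutation-model chance-corrected agreement computed from the
#' contingency table. Returns 1 when both partitions are trivial and
#' identical in structure (degenerate denominator).
#'
#' @param labels_a,labels_b cluster label vectors of equal length.
#' @return ARI (1 = identical partitions, ~0 = chance agreement).
#' @export
adjusted_rand_index <- function(labels_a, labels_b) {
  if (length(labels_a) != length(labels_b))
    stopf("label vectors must have equal length")
  n <- length(labels_a)
  tab <- table(labels_a, labels_b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  expected <- sum_a * sum_b / comb2(n)
  maximum <- (sum_a + sum_b) / 2
  if (abs(maximum - expected) < .Machine$double.eps * 4) return(1)
  (sum_ij - expected) / (maximum - expected)
}

#' Calinski-Harabasz index
#'
#' Between-cluster dispersion over within-cluster dispersion, each normalized
#' by its degrees of freedom; dispersions are traces of the scatter matrices.
#' Higher is better separated. Zero within-cluster variance with distinct
#' centroids is degenerate and returns `Inf` with a warning.
#'
#' @param x numeric matrix, one row per observation.
#' @param labels cluster labels, one per row; needs `2 <= k < n`.
#' @return CH index.
#' @export
calinski_harabasz <- function(x, labels) {
  x <- as.matrix(x)
  n <- nrow(x)
  labels <- as.character(labels)
  if (length(labels) != n) stopf("one label per row required")
  k <- length(unique(labels))
  if (k < 2 || k >= n) stopf("need 2 <= k < n clusters (k=%d, n=%d)", k, n)
  grand <- colMeans(x)
  ssb <- 0
  ssw <- 0
  for (g in unique(labels)) {
    xi <- x[labels == g, , drop = FALSE]
    ci <- colMeans(xi)
    ssb <- ssb + nrow(xi) * sum((ci - grand)^2)
    ssw <- ssw + sum(sweep(xi, 2, ci)^2)
  }
  if (ssw == 0) {
    warnf("zero within-cluster dispersion: CH index is degenerate (Inf)")
    return(Inf)
  }
  (ssb / (k - 1)) / (ssw / (n - k))
}
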