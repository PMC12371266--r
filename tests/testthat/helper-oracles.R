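# Independent brute-force oracles: deliberately naive implementations
# (threshold enumeration, exhaustive pair counting) kept separate from the
# package's vectorized code paths.

auprc_brute <- function(scores, labels) {
  thresholds <- sort(unique(scores), decreasing = TRUE)
  n_pos <- sum(labels == 1)
  ap <- 0
  prev_recall <- 0
  for (t in thresholds) {
    sel <- scores >= t
    precision <- sum(labels[sel] == 1) / sum(sel)
    recall <- sum(labels[sel] == 1) / n_pos
    ap <- ap + precision * (recall - prev_recall)
    prev_recall <- recall
  }
  ap
}

auroc_brute <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) {
    for (q in neg) {
      if (p > q) total <- total + 1
      else if (p == q) total <- total + 0.5
    }
  }
  total / (length(pos) * length(neg))
}

ari_brute <- function(la, lb) {
  n <- length(la)
  tog_a <- 0; tog_b <- 0; tog_ab <- 0; tot <- 0
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      sa <- la[i] == la[j]
      sb <- lb[i] == lb[j]
      tog_a <- tog_a + sa
      tog_b <- tog_b + sb
      tog_ab <- tog_ab + (sa && sb)
      tot <- tot + 1
    }
  }
  expected <- tog_a * tog_b / tot
  maximum <- (tog_a + tog_b) / 2
  if (abs(maximum - expected) < 1e-12) return(1)
  (tog_ab - expected) / (maximum - expected)
}

ch_brute <- function(x, labels) {
  x <- as.matrix(x)
  n <- nrow(x)
  k <- length(unique(labels))
  grand <- colMeans(x)
  ssb <- 0; ssw <- 0
  for (g in unique(labels)) {
    rows <- which(labels == g)
    cen <- colMeans(x[rows, , drop = FALSE])
    ssb <- ssb + length(rows) * sum((cen - grand)^2)
    for (i in rows) ssw <- ssw + sum((x[i, ] - cen)^2)
  }
  (ssb / (k - 1)) / (ssw / (n - k))
}

# two-sample Kolmogorov-Smirnov statistic (no p-value needed)
ks_stat <- function(a, b) {
  pts <- sort(unique(c(a, b)))
  max(abs(vapply(pts, function(p) mean(a <= p) - mean(b <= p), numeric(1))))
}
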