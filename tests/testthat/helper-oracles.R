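# Independent oracles, kept deliberately naive.

# exhaustive minimum within-cluster sum of squares over all 2-cluster
# partitions (point 1 anchored to group 1; both groups non-empty)
brute_min_wcss <- function(x) {
  x <- as.matrix(x)
  n <- nrow(x)
  stopifnot(n >= 2, n <= 12)
  wcss <- function(g) {
    sum(vapply(unique(g), function(k) {
      m <- x[g == k, , drop = FALSE]
      sum(sweep(m, 2, colMeans(m))^2)
    }, numeric(1)))
  }
  best <- Inf
  for (m in 0:(2^(n - 1) - 2)) {
    g <- c(TRUE, as.logical(bitwAnd(m, 2^(0:(n - 2)))))
    best <- min(best, wcss(as.integer(g)))
  }
  best
}

# all-pairs Mann-Whitney AUC with half-credit ties
brute_auc <- function(scores, labels) {
  cases <- scores[labels == 1]
  controls <- scores[labels == 0]
  stopifnot(length(cases) > 0, length(controls) > 0)
  total <- 0
  for (a in cases) for (b in controls) {
    total <- total + (a > b) + 0.5 * (a == b)
  }
  total / (length(cases) * length(controls))
}
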