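# Independent brute-force oracles.

# Exhaustive pairwise-slope Passing-Bablok slope: plain loops, explicit
# offset-median selection.
pb_slope_oracle <- function(x, y) {
  n <- length(x)
  slopes <- c()
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      dx <- x[j] - x[i]
      dy <- y[j] - y[i]
      if (dx == 0 && dy == 0) next
      s <- if (dx == 0) sign(dy) * Inf else dy / dx
      if (s == -1) next
      slopes <- c(slopes, s)
    }
  }
  slopes <- sort(slopes)
  k <- 0
  for (s in slopes) if (s < -1) k <- k + 1
  m <- length(slopes)
  if (m %% 2 == 1) slopes[(m + 1) / 2 + k]
  else (slopes[m / 2 + k] + slopes[m / 2 + 1 + k]) / 2
}

# O(n^2) pair-counting AUC with half-credit ties.
auc_oracle <- function(scores, truth) {
  pos <- scores[truth]
  neg <- scores[!truth]
  total <- 0
  for (p in pos) {
    for (q in neg) {
      total <- total + (p > q) + 0.5 * (p == q)
    }
  }
  total / (length(pos) * length(neg))
}
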