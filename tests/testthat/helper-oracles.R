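# Independent oracles, coded directly from the definitions and kept free
# of the package's implementation.

# Brute-force Jaro: greedy left-to-right matching within the window,
# transpositions from comparing the two matched subsequences.
jaro_oracle <- function(a, b) {
  la <- length(a); lb <- length(b)
  w <- max(floor(max(la, lb) / 2) - 1, 0)
  used <- logical(lb)
  ai <- integer(0); bj <- integer(0)
  for (i in seq_len(la)) {
    lo <- max(1L, i - w); hi <- min(lb, i + w)
    if (lo > hi) next
    for (j in lo:hi) {
      if (!used[j] && identical(a[i], b[j])) {
        used[j] <- TRUE
        ai <- c(ai, i); bj <- c(bj, j)
        break
      }
    }
  }
  m <- length(ai)
  if (m == 0) return(list(similarity = 0, m = 0L, t = 0))
  t <- sum(a[ai] != b[sort(bj)]) / 2
  list(similarity = (m / la + m / lb + (m - t) / m) / 3, m = m, t = t)
}

# Midrank Spearman coded from first principles.
spearman_oracle <- function(x, y) {
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  mean_rx <- mean(rx); mean_ry <- mean(ry)
  sum((rx - mean_rx) * (ry - mean_ry)) /
    sqrt(sum((rx - mean_rx)^2) * sum((ry - mean_ry)^2))
}

# All token sequences over `alphabet` of lengths 1..max_len.
enumerate_sequences <- function(alphabet, max_len) {
  out <- list()
  for (L in seq_len(max_len)) {
    g <- do.call(expand.grid,
                 c(rep(list(alphabet), L),
                   list(stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)))
    for (r in seq_len(nrow(g))) {
      out[[length(out) + 1L]] <- unlist(g[r, ], use.names = FALSE)
    }
  }
  out
}

# Random token sequence over the phrase alphabet.
random_sequence <- function(max_len = 15) {
  n <- sample.int(max_len, 1)
  sample(phrase_alphabet(), n, replace = TRUE)
}
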