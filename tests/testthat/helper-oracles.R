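# Independent oracle implementations, deliberately written from the raw
# definitions (slow loops / sample-level encodings) so they share no code
# with the package's closed-form paths.

# CEN straight from the per-class probability definitions
cenOracle <- function(m) {
  k <- nrow(m)
  S <- sum(m)
  base <- 2 * (k - 1)
  total <- 0
  for (j in seq_len(k)) {
    d <- sum(m[j, ]) + sum(m[, j])
    if (d == 0) next
    pj <- d / (2 * S)
    cenj <- 0
    for (i in seq_len(k)) {
      if (i == j) next
      for (p in c(m[j, i] / d, m[i, j] / d)) {
        if (p > 0) cenj <- cenj - p * log(p, base = base)
      }
    }
    total <- total + pj * cenj
  }
  total
}

# multiclass MCC as the correlation between the sample-level indicator
# encodings of predicted (X) and true (Y) class membership
mccIndicatorOracle <- function(m) {
  k <- nrow(m)
  stopifnot(all(m == round(m)))
  n <- sum(m)
  X <- matrix(0, n, k)
  Y <- matrix(0, n, k)
  s <- 0L
  for (i in seq_len(k)) for (j in seq_len(k)) {
    cnt <- m[i, j]
    if (cnt > 0) {
      rows <- s + seq_len(cnt)
      Y[rows, i] <- 1
      X[rows, j] <- 1
      s <- s + cnt
    }
  }
  covSum <- function(A, B) {
    tot <- 0
    for (l in seq_len(k))
      tot <- tot + mean(A[, l] * B[, l]) - mean(A[, l]) * mean(B[, l])
    tot
  }
  den <- sqrt(covSum(X, X)) * sqrt(covSum(Y, Y))
  if (den == 0) return(0)
  covSum(X, Y) / den
}

# random non-negative integer matrix with positive total
randIntMatrix <- function(k, maxEntry = 20L) {
  repeat {
    m <- matrix(sample(0:maxEntry, k * k, replace = TRUE), k, k)
    if (sum(m) > 0) return(m)
  }
}

# random strictly positive matrix (no zero rows/columns)
randPosMatrix <- function(k, maxEntry = 20L) {
  matrix(sample(seq_len(maxEntry), k * k, replace = TRUE), k, k)
}
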