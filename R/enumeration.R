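# Exhaustive confusion-matrix enumeration: all k x k non-negative integer
# matrices with fixed row sums (per-class sample counts), and the cumulative
# set of 2 x 2 matrices up to a total sample bound.

#' Compositions of an integer into k non-negative parts
#'
#' All ways of writing \code{n} as an ordered sum of \code{k} non-negative
#' integers, in colexicographic order (the last part varies slowest; the
#' first rows are (n,0,...,0), (n-1,1,0,...,0), ...).
#'
#' @param n non-negative integer.
#' @param k number of parts (k >= 1).
#' @return integer matrix with \code{choose(n + k - 1, k - 1)} rows and
#'   \code{k} columns.
#' @export
compositions <- function(n, k) {
  n <- as.integer(n); k <- as.integer(k)
  if (is.na(n) || n < 0L) inputError("n must be a non-negative integer")
  if (is.na(k) || k < 1L) inputError("k must be a positive integer")
  if (k == 1L) return(matrix(n, 1L, 1L))
  blocks <- lapply(0:n, function(last) {
    rest <- compositions(n - last, k - 1L)
    cbind(rest, rep.int(last, nrow(rest)), deparse.level = 0)
  })
  do.call(rbind, blocks)
}

#' Count matrices with fixed row sums
#'
#' Closed-form size of the fixed-row-sum enumeration:
#' \eqn{\prod_i \binom{s_i + k - 1}{k - 1}} for row sums \eqn{s_i} and
#' dimension k.
#'
#' @param rowSums integer vector of per-class (true-class) sample counts;
#'   all >= 0, at least one positive. Its length fixes k.
#' @return the number of k x k non-negative integer matrices with those row
#'   sums.
#' @examples
#' countFixedRowSums(c(2, 1, 1))  # 54
#' @export
countFixedRowSums <- function(rowSums) {
  rowSums <- as.integer(rowSums)
  k <- length(rowSums)
  if (k < 2L) inputError("rowSums must have length >= 2")
  if (any(is.na(rowSums)) || any(rowSums < 0L) || sum(rowSums) < 1L)
    inputError("rowSums must be non-negative with a positive total")
  prod(choose(rowSums + k - 1, k - 1))
}

#' Enumerate matrices with fixed row sums
#'
#' Yields every k x k non-negative integer matrix whose i-th row sums to
#' \code{rowSums[i]}, each exactly once, in row-wise colexicographic order:
#' matrices are ordered by the colex rank of row 1 (fastest), then row 2,
#' and so on. With a callback the matrices are streamed in constant memory;
#' otherwise they are returned as a list.
#'
#' @inheritParams countFixedRowSums
#' @param FUN optional function applied to each matrix in order; its results
#'   are discarded (stream for side effects or closures).
#' @return with \code{FUN}: the number of matrices streamed, invisibly;
#'   without: a list of matrices.
#' @examples
#' length(enumerateFixedRowSums(c(1, 1)))  # 4
#' @export
enumerateFixedRowSums <- function(rowSums, FUN = NULL) {
  total <- countFixedRowSums(rowSums)
  rowSums <- as.integer(rowSums)
  k <- length(rowSums)
  rows <- lapply(rowSums, compositions, k = k)
  sizes <- vapply(rows, nrow, 0L)
  collect <- is.null(FUN)
  if (collect) {
    if (total > 2e5) inputError(
      "enumeration too large to materialise; supply FUN to stream")
    out <- vector("list", total)
  }
  idx <- rep.int(1L, k)
  for (t in seq_len(total)) {
    m <- matrix(0, k, k)
    for (i in seq_len(k)) m[i, ] <- rows[[i]][idx[i], ]
    if (collect) out[[t]] <- m else FUN(m)
    # advance the mixed-radix counter, row 1 fastest
    for (i in seq_len(k)) {
      idx[i] <- idx[i] + 1L
      if (idx[i] <= sizes[i]) break
      idx[i] <- 1L
    }
  }
  if (collect) out else invisible(total)
}

#' Measure table over a fixed-row-sum enumeration
#'
#' Streams [enumerateFixedRowSums()] and evaluates the requested measures on
#' every matrix, returning one row per matrix: the flattened entries
#' (row-major: x11 is row 1 column 1) followed by the measure columns.
#'
#' @inheritParams countFixedRowSums
#' @param measures subset of \code{c("acc", "mcc", "cen")}.
#' @return a data.frame with \code{countFixedRowSums(rowSums)} rows.
#' @export
measureTable <- function(rowSums, measures = c("acc", "mcc", "cen")) {
  measures <- match.arg(measures, several.ok = TRUE)
  total <- countFixedRowSums(rowSums)
  if (total > 1e6) inputError("enumeration too large for a measure table")
  k <- length(rowSums)
  ent <- matrix(0, total, k * k)
  vals <- matrix(0, total, length(measures))
  t <- 0L
  enumerateFixedRowSums(rowSums, function(m) {
    t <<- t + 1L
    ent[t, ] <<- as.vector(t(m))
    vals[t, ] <<- vapply(measures, function(ms) switch(ms,
      acc = .accMatrix(m), mcc = .mccMatrix(m), cen = .cenMatrix(m)), 0)
  })
  colnames(ent) <- paste0("x", rep(seq_len(k), each = k), rep(seq_len(k), k))
  colnames(vals) <- measures
  data.frame(ent, vals)
}

#' Count the cumulative binary enumeration
#'
#' Closed-form number of 2 x 2 non-negative integer matrices with total in
#' \code{1..maxTotal}: \eqn{\binom{maxTotal + 4}{4} - 1}. At the default
#' study bound of 100 this is 4 598 125.
#'
#' @param maxTotal positive integer bound on the total sample count.
#' @return a count.
#' @examples
#' countBinaryCumulative(100)  # 4598125
#' @export
countBinaryCumulative <- function(maxTotal) {
  maxTotal <- as.integer(maxTotal)
  if (is.na(maxTotal) || maxTotal < 1L) inputError("maxTotal must be >= 1")
  choose(maxTotal + 4, 4) - 1
}

# all (tp, fn, fp, tn) with tp + fn + fp + tn == total, as a 4-column
# matrix; vectorised, used to stream the binary study in chunks
.binaryTuples <- function(total) {
  u <- rep.int(0:total, 1:(total + 1L))       # tp + fn
  tp <- sequence(1:(total + 1L)) - 1L
  fn <- u - tp
  reps <- total - u + 1L                      # choices for fp
  tp <- rep.int(tp, reps)
  fn <- rep.int(fn, reps)
  fp <- sequence(reps) - 1L
  tn <- total - tp - fn - fp
  cbind(tp = tp, fn = fn, fp = fp, tn = tn)
}

#' Enumerate the cumulative binary set
#'
#' Yields every 2 x 2 non-negative integer matrix with total in
#' \code{1..maxTotal} exactly once (grouped by total, ascending). With a
#' callback the matrices are streamed; otherwise returned as a list (small
#' bounds only).
#'
#' @inheritParams countBinaryCumulative
#' @param FUN optional function applied to each matrix
#'   \code{rbind(c(tp, fn), c(fp, tn))}.
#' @return with \code{FUN}: the number streamed, invisibly; without: a list.
#' @export
enumerateBinaryCumulative <- function(maxTotal, FUN = NULL) {
  n <- countBinaryCumulative(maxTotal)
  collect <- is.null(FUN)
  if (collect) {
    if (n > 2e5) inputError(
      "enumeration too large to materialise; supply FUN to stream")
    out <- vector("list", n)
  }
  t <- 0L
  for (s in seq_len(maxTotal)) {
    tup <- .binaryTuples(s)
    for (r in seq_len(nrow(tup))) {
      m <- rbind(c(tup[r, 1L], tup[r, 2L]), c(tup[r, 3L], tup[r, 4L]))
      t <- t + 1L
      if (collect) out[[t]] <- m else FUN(m)
    }
  }
  if (collect) out else invisible(t)
}
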