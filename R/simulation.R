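# Random confusion-matrix generator and the two relation studies: the
# multiclass tMCC vs scaled-CEN study and the exhaustive binary CEN vs MCC
# study.

#' Configuration of the random confusion-matrix generator
#'
#' One matrix is generated as: dimension k uniform on \code{dimRange}; each
#' diagonal entry (correctly classified count per class) a uniform integer
#' in \code{1..diagMax}; a per-matrix misclassification parameter a uniform
#' on \code{aRange}; each off-diagonal entry of row i a uniform integer in
#' \code{1..ceiling(a * d_i)} where d_i is the row's diagonal entry. The
#' defaults (k in 3..30, diagonal up to 1000, a in (0, 0.1), the
#' small-to-moderate misclassification regime) are the conditions of the
#' 200 000-matrix relation study.
#'
#' @param nMatrices number of matrices to generate.
#' @param dimRange integer (min, max) for the dimension; min >= 3.
#' @param diagMax upper bound for diagonal entries.
#' @param aRange (min, max) for the misclassification parameter a.
#' @param seed integer master seed; mandatory.
#' @return a list of class \code{"mccenSimConfig"}.
#' @export
simulationConfig <- function(nMatrices, dimRange = c(3L, 30L),
                             diagMax = 1000L, aRange = c(0, 0.1), seed) {
  if (missing(seed)) inputError("seed is required")
  nMatrices <- as.integer(nMatrices)
  dimRange <- as.integer(dimRange)
  diagMax <- as.integer(diagMax)
  if (is.na(nMatrices) || nMatrices < 1L) inputError("nMatrices must be >= 1")
  if (length(dimRange) != 2L || any(is.na(dimRange)) ||
      dimRange[1] < 3L || dimRange[2] < dimRange[1])
    inputError("dimRange must be (min, max) with min >= 3")
  if (is.na(diagMax) || diagMax < 1L) inputError("diagMax must be >= 1")
  if (length(aRange) != 2L || any(!is.finite(aRange)) ||
      aRange[1] < 0 || aRange[2] <= aRange[1])
    inputError("aRange must be a nonempty interval of non-negative reals")
  structure(list(nMatrices = nMatrices, dimRange = dimRange,
                 diagMax = diagMax, aRange = aRange,
                 seed = as.integer(seed)),
            class = "mccenSimConfig")
}

# the off-diagonal upper bound rule, isolated so the generation scheme is
# pinned in one place: row i of a matrix with diagonal d gets entries
# uniform on 1..ceiling(a * d_i) (at least 1)
.offdiagBound <- function(a, diagEntries) {
  pmax(1L, as.integer(ceiling(a * diagEntries)))
}

#' Generate random confusion matrices
#'
#' Streams \code{config$nMatrices} random matrices (bare numeric matrices,
#' rows = true class) to \code{FUN} in a deterministic order fixed by the
#' seed: two runs with the same configuration produce identical streams,
#' and the first n matrices of a longer run equal those of a shorter one.
#'
#' @param config a [simulationConfig()].
#' @param FUN function applied to each matrix; results discarded.
#' @return the number of matrices generated, invisibly.
#' @export
generateRandomMatrices <- function(config, FUN) {
  if (!inherits(config, "mccenSimConfig"))
    inputError("config must come from simulationConfig()")
  set.seed(config$seed)
  kMin <- config$dimRange[1]; kMax <- config$dimRange[2]
  for (t in seq_len(config$nMatrices)) {
    k <- if (kMax > kMin) sample(kMin:kMax, 1L) else kMin
    dg <- sample.int(config$diagMax, k, replace = TRUE)
    a <- stats::runif(1L, config$aRange[1], config$aRange[2])
    bound <- .offdiagBound(a, dg)
    m <- matrix(0, k, k)
    for (i in seq_len(k)) m[i, -i] <- sample.int(bound[i], k - 1L, replace = TRUE)
    diag(m) <- dg
    FUN(m)
  }
  invisible(config$nMatrices)
}

#' Multiclass tMCC vs scaled-CEN relation study
#'
#' Generates random confusion matrices, computes MCC, CEN, tMCC and the
#' dimension-scaled CEN (k/(k-1) CEN) for each, and summarises the relation
#' between tMCC and scaled CEN: Pearson correlation, mean elementwise ratio
#' tMCC / scaled CEN with a 95 percent Student bootstrap interval, degree of
#' consistency (both lower-better) and degree of discriminancy.
#'
#' @param config a [simulationConfig()].
#' @param nBoot bootstrap replicates for the ratio interval.
#' @return a [StudyReport-class] whose table has one row per matrix with
#'   columns k, mcc, cen, tmcc, scaled_cen.
#' @export
runMulticlassRelationStudy <- function(config, nBoot = 1000L) {
  n <- config$nMatrices
  k <- integer(n); mccV <- cenV <- tmccV <- scenV <- numeric(n)
  t <- 0L
  generateRandomMatrices(config, function(m) {
    t <<- t + 1L
    kk <- nrow(m)
    k[t] <<- kk
    mccV[t] <<- .mccMatrix(m)
    cenV[t] <<- .cenMatrix(m)
    tmccV[t] <<- tmcc(mccV[t], kk, policy = "clamp")
    scenV[t] <<- kk / (kk - 1) * cenV[t]
  })
  # exact tie detection: ties between continuous-valued measures on random
  # matrices are exact-coincidence events; binning at a finite tolerance
  # would manufacture spurious ties by birthday collisions at this n
  summary <- relationSummary(tmccV, scenV, nBoot = nBoot,
                             seed = config$seed + 1L, tieTol = 0,
                             fLowerBetter = TRUE, gLowerBetter = TRUE)
  new("StudyReport",
      table = data.frame(k = k, mcc = mccV, cen = cenV, tmcc = tmccV,
                         scaled_cen = scenV),
      summary = summary)
}

# vectorised binary measures over (tp, fn, fp, tn) columns
.binaryMccVec <- function(tp, fn, fp, tn) {
  num <- tp * tn - fp * fn
  den <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  ifelse(den > 0, num / sqrt(pmax(den, 1)), 0)
}

.binaryCenVec <- function(tp, fn, fp, tn) {
  S <- tp + fn + fp + tn
  d1 <- 2 * tp + fn + fp
  d2 <- 2 * tn + fn + fp
  h <- function(x, d) {
    p <- ifelse(d > 0, x / pmax(d, 1), 0)
    ifelse(p > 0, -p * log2(p), 0)
  }
  c1 <- h(fn, d1) + h(fp, d1)
  c2 <- h(fn, d2) + h(fp, d2)
  d1 / (2 * S) * c1 + d2 / (2 * S) * c2
}

#' Exhaustive binary CEN vs MCC study
#'
#' Streams every 2 x 2 confusion matrix with total sample count in
#' \code{1..maxTotal} (4 598 125 matrices at the default bound of 100),
#' computing MCC and CEN for each in vectorised chunks grouped by total.
#' Returns the Pearson correlation between the two measures over the
#' cumulative set (accumulated from online sums, in constant memory) and
#' over the per-total subsets of interest.
#'
#' @param maxTotal bound on the total sample count.
#' @param subsetTotals totals for which per-subset correlations are also
#'   reported (those not exceeding \code{maxTotal}).
#' @param keepTable materialise the full per-matrix table (only sensible
#'   for small bounds; used e.g. to check order independence).
#' @return a [StudyReport-class]; the table has one row per subset total
#'   (columns s, n, pearson) plus a cumulative row, unless
#'   \code{keepTable = TRUE}, in which case it has one row per matrix. The
#'   summary holds the cumulative Pearson correlation; its item count is
#'   the streamed matrix count.
#' @export
runBinaryStudy <- function(maxTotal = 100L, subsetTotals = c(5L, 10L, 50L, 75L),
                           keepTable = FALSE) {
  maxTotal <- as.integer(maxTotal)
  if (is.na(maxTotal) || maxTotal < 1L) inputError("maxTotal must be >= 1")
  subsetTotals <- intersect(as.integer(subsetTotals), seq_len(maxTotal))
  if (keepTable && countBinaryCumulative(maxTotal) > 2e5)
    inputError("keepTable only supported for small maxTotal")
  n <- 0; sx <- sy <- sxx <- syy <- sxy <- 0
  subRows <- list(); full <- list()
  for (s in seq_len(maxTotal)) {
    tup <- .binaryTuples(s)
    x <- .binaryMccVec(tup[, 1L], tup[, 2L], tup[, 3L], tup[, 4L])
    y <- .binaryCenVec(tup[, 1L], tup[, 2L], tup[, 3L], tup[, 4L])
    n <- n + length(x)
    sx <- sx + sum(x); sy <- sy + sum(y)
    sxx <- sxx + sum(x^2); syy <- syy + sum(y^2); sxy <- sxy + sum(x * y)
    if (s %in% subsetTotals)
      subRows[[as.character(s)]] <- data.frame(
        s = s, n = length(x), pearson = stats::cor(x, y))
    if (keepTable)
      full[[s]] <- data.frame(tp = tup[, 1L], fn = tup[, 2L], fp = tup[, 3L],
                              tn = tup[, 4L], mcc = x, cen = y)
  }
  cov <- sxy / n - (sx / n) * (sy / n)
  vx <- sxx / n - (sx / n)^2
  vy <- syy / n - (sy / n)^2
  pearson <- if (vx > 0 && vy > 0) cov / sqrt(vx * vy) else NA_real_
  tab <- if (keepTable) do.call(rbind, full) else
    rbind(do.call(rbind, subRows),
          data.frame(s = NA_integer_, n = n, pearson = pearson))
  summary <- new("ComparisonReport", nItems = as.integer(n),
                 discriminancy = NA_real_, consistency = NA_real_,
                 pearson = pearson, meanRatio = NA_real_,
                 ratioCI = c(NA_real_, NA_real_), nBoot = 0L)
  new("StudyReport", table = tab, summary = summary)
}
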