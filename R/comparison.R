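# Huang-Ling order statistics for comparing two performance measures over
# the same collection of matrices, plus the correlation / ratio summaries
# used in the tMCC-CEN relation study.

# group key for tie detection: exact equality when tieTol = 0, otherwise
# values are binned at resolution tieTol (default 1e-9, fine enough that
# algebraically distinct measure values of small integer matrices never
# merge, coarse enough that floating-point noise never splits a true tie)
.tieKey <- function(x, tieTol) {
  if (tieTol <= 0) return(sprintf("%a", x))   # exact (hex representation)
  as.character(round(x / tieTol))
}

.tiePairs <- function(key) {
  n <- table(key)
  sum(choose(n, 2))
}

#' Degree of discriminancy
#'
#' Huang-Ling criterion for how much more finely measure f separates a
#' collection than measure g: the number of unordered pairs on which f
#' differs while g ties, divided by the number on which g differs while f
#' ties. Values above 1 mean f discriminates more. Undefined (NA) when the
#' denominator is empty - f never ties where g separates.
#'
#' @param valuesF,valuesG equal-length numeric vectors: the two measures
#'   evaluated on the same matrices (orientation does not matter here).
#' @param tieTol absolute tolerance for tie detection; 0 means exact
#'   equality.
#' @return a positive number, or NA when undefined.
#' @examples
#' degreeOfDiscriminancy(c(1, 1, 2), c(1, 2, 2))  # 1
#' @export
degreeOfDiscriminancy <- function(valuesF, valuesG, tieTol = 1e-9) {
  if (length(valuesF) != length(valuesG))
    inputError("value sequences must have equal length")
  if (length(valuesF) < 2L) inputError("need at least 2 values")
  kf <- .tieKey(valuesF, tieTol)
  kg <- .tieKey(valuesG, tieTol)
  tiesF <- .tiePairs(kf)
  tiesG <- .tiePairs(kg)
  tiesBoth <- .tiePairs(paste(kf, kg, sep = "|"))
  num <- tiesG - tiesBoth   # g ties, f differs
  den <- tiesF - tiesBoth   # f ties, g differs
  if (den == 0) return(NA_real_)
  num / den
}

# orientation-align a sequence: lower-better measures are negated so that
# "better" always means larger before pair-order comparison
.orient <- function(x, lowerBetter) if (lowerBetter) -x else x

#' Degree of consistency
#'
#' Fraction of unordered pairs ordered the same way by both measures, among
#' all pairs ordered (in either direction) by both. Pairs tied on either
#' measure are excluded. Both sequences are first orientation-aligned, so a
#' higher-better measure (MCC) can be compared with a lower-better one
#' (CEN, tMCC).
#'
#' @inheritParams degreeOfDiscriminancy
#' @param fLowerBetter,gLowerBetter whether smaller values of the measure
#'   mean better classification.
#' @return a number in [0, 1], or NA when no pair is ordered by both.
#' @examples
#' degreeOfConsistency(c(1, 2, 3), c(1, 3, 2))  # 2/3
#' @export
degreeOfConsistency <- function(valuesF, valuesG, tieTol = 1e-9,
                                fLowerBetter = FALSE, gLowerBetter = FALSE) {
  if (length(valuesF) != length(valuesG))
    inputError("value sequences must have equal length")
  n <- length(valuesF)
  if (n < 2L) inputError("need at least 2 values")
  if (n > 10000L)
    inputError("pairwise consistency above 10000 items; subsample first")
  f <- .orient(valuesF, fLowerBetter)
  g <- .orient(valuesG, gLowerBetter)
  df <- outer(f, f, "-")[upper.tri(diag(n))]
  dg <- outer(g, g, "-")[upper.tri(diag(n))]
  sf <- sign(df) * (abs(df) > tieTol)
  sg <- sign(dg) * (abs(dg) > tieTol)
  prod <- sf * sg
  concordant <- sum(prod > 0)
  discordant <- sum(prod < 0)
  if (concordant + discordant == 0) return(NA_real_)
  concordant / (concordant + discordant)
}

#' Relation summary between two measures
#'
#' Pearson correlation, mean elementwise ratio f/g (over pairs with g != 0)
#' with a 95 percent Student bootstrap interval, plus the discriminancy and
#' a (possibly subsampled) consistency degree, bundled as a
#' [ComparisonReport-class].
#'
#' @inheritParams degreeOfConsistency
#' @param nBoot bootstrap replicates for the mean-ratio interval.
#' @param seed seed for the bootstrap resampling (and the consistency
#'   subsample); mandatory, there is no silent nondeterminism.
#' @param consistencySample pairwise consistency is computed on at most this
#'   many items, drawn without replacement when the collection is larger.
#' @return a [ComparisonReport-class].
#' @export
relationSummary <- function(valuesF, valuesG, nBoot = 1000L, seed,
                            tieTol = 1e-9, fLowerBetter = FALSE,
                            gLowerBetter = FALSE, consistencySample = 2000L) {
  if (missing(seed)) inputError("seed is required for the bootstrap")
  n <- length(valuesF)
  if (length(valuesG) != n) inputError("value sequences must have equal length")
  if (n < 3L) inputError("need at least 3 values")
  pearson <- if (stats::sd(valuesF) == 0 || stats::sd(valuesG) == 0)
    NA_real_ else stats::cor(valuesF, valuesG)
  ok <- valuesG != 0
  ratios <- valuesF[ok] / valuesG[ok]
  meanRatio <- mean(ratios)
  set.seed(as.integer(seed))
  bootMeans <- vapply(seq_len(nBoot), function(i)
    mean(ratios[sample.int(length(ratios), replace = TRUE)]), 0)
  half <- stats::qt(0.975, df = nBoot - 1L) * stats::sd(bootMeans)
  ci <- c(meanRatio - half, meanRatio + half)
  idx <- if (n > consistencySample)
    sample.int(n, consistencySample) else seq_len(n)
  consistency <- degreeOfConsistency(valuesF[idx], valuesG[idx], tieTol,
                                     fLowerBetter, gLowerBetter)
  disc <- degreeOfDiscriminancy(valuesF, valuesG, tieTol)
  new("ComparisonReport", nItems = as.integer(n), discriminancy = disc,
      consistency = consistency, pearson = pearson, meanRatio = meanRatio,
      ratioCI = ci, nBoot = as.integer(nBoot))
}

#' Discriminancy study on a fixed-row-sum enumeration
#'
#' Enumerates every 3-class (or k-class) confusion matrix with the given
#' per-class sample counts, evaluates CEN and MCC on each, and returns the
#' Huang-Ling degree of discriminancy of CEN over MCC together with the tie
#' counts behind it. The default counts (7, 3, 1) are the small-sample
#' worked example where the degree is about 6.
#'
#' @inheritParams countFixedRowSums
#' @param tieTol tie tolerance passed to the pair counting.
#' @return a list with the number of matrices, the two tie-pair counts and
#'   \code{discriminancy} = (MCC ties, CEN differs) / (CEN ties, MCC
#'   differs).
#' @export
discriminancyStudy <- function(rowSums = c(7, 3, 1), tieTol = 1e-9) {
  tab <- measureTable(rowSums, c("mcc", "cen"))
  kf <- .tieKey(tab$cen, tieTol)
  kg <- .tieKey(tab$mcc, tieTol)
  tiesCen <- .tiePairs(kf)
  tiesMcc <- .tiePairs(kg)
  tiesBoth <- .tiePairs(paste(kf, kg, sep = "|"))
  num <- tiesMcc - tiesBoth
  den <- tiesCen - tiesBoth
  list(nMatrices = nrow(tab), mccTiePairsCenDiffers = num,
       cenTiePairsMccDiffers = den,
       discriminancy = if (den == 0) NA_real_ else num / den)
}
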