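#' @import methods
NULL

# classed conditions so the CLI can map failures to exit codes
inputError <- function(msg) {
  stop(structure(list(message = msg, call = NULL),
                 class = c("mccen_input_error", "error", "condition")))
}

domainError <- function(msg) {
  stop(structure(list(message = msg, call = NULL),
                 class = c("mccen_domain_error", "error", "condition")))
}

#' ConfusionMatrix class
#'
#' A square non-negative matrix of classification outcomes. Rows index the
#' true class, columns the predicted class: entry \code{(i, j)} is the number
#' of samples of true class \code{i} that the classifier assigned to class
#' \code{j}. Entries may be real-valued, not just integer: all measures in
#' this package are invariant under multiplication of the whole matrix by a
#' positive scalar, so normalised matrices are legitimate inputs.
#'
#' @slot counts numeric k x k matrix of non-negative entries with positive sum.
#' @slot labels character vector of the k ordered class identifiers.
#'
#' @seealso [confusionMatrix()], [accuracy()], [mcc()], [cen()]
#' @export
setClass("ConfusionMatrix",
         representation(counts = "matrix", labels = "character"))

setValidity("ConfusionMatrix", function(object) {
  m <- object@counts
  if (!is.numeric(m)) return("counts must be numeric")
  if (nrow(m) != ncol(m)) return("counts must be a square matrix")
  if (nrow(m) < 2L) return("at least 2 classes are required")
  if (any(!is.finite(m))) return("all entries must be finite")
  if (any(m < 0)) return("all entries must be non-negative")
  if (sum(m) <= 0) return("total count must be positive")
  if (length(object@labels) != nrow(m)) return("labels length must equal the matrix dimension")
  if (anyDuplicated(object@labels)) return("class labels must be unique")
  TRUE
})

#' ClassProfile class
#'
#' Per-class ingredients of the Confusion Entropy for one class j: the
#' confusion probability of the class, the two vectors of misclassification
#' probabilities (class j mistaken for others, others mistaken for class j),
#' and the per-class entropy they induce.
#'
#' @slot classIndex integer index j of the class (1-based).
#' @slot pj confusion probability of class j; the pj sum to 1 over classes.
#' @slot pTrueToPred probabilities of classifying samples of class j as each
#'   other class (row j off-diagonal, normalised by the row-plus-column mass
#'   of class j).
#' @slot pPredFromTrue probabilities of classifying samples of each other
#'   class as class j (column j off-diagonal, same normalisation).
#' @slot cenj per-class confusion entropy, logarithm base 2(k-1).
#' @export
setClass("ClassProfile",
         representation(classIndex = "integer", pj = "numeric",
                        pTrueToPred = "numeric", pPredFromTrue = "numeric",
                        cenj = "numeric"))

#' MetricsReport class
#'
#' Scalar performance measures of one confusion matrix.
#'
#' @slot acc accuracy in [0, 1].
#' @slot mcc multiclass Matthews Correlation Coefficient in [-1, 1].
#' @slot cen Confusion Entropy (non-negative; at most 1 for k >= 3 classes,
#'   possibly above 1 for binary matrices).
#' @slot tmcc transformed MCC, or NA when the MCC value lies outside the
#'   transform's domain.
#' @slot nClasses integer number of classes.
#' @slot total sum of all matrix entries.
#' @export
setClass("MetricsReport",
         representation(acc = "numeric", mcc = "numeric", cen = "numeric",
                        tmcc = "numeric", nClasses = "integer", total = "numeric"))

#' ComparisonReport class
#'
#' Pairwise order statistics between two measures evaluated on the same
#' collection of confusion matrices.
#'
#' @slot nItems number of paired values.
#' @slot discriminancy Huang-Ling degree of discriminancy of the first
#'   measure over the second; NA when undefined (no pairs tie on the first
#'   measure while separating on the second).
#' @slot consistency Huang-Ling degree of consistency in [0, 1]; NA when no
#'   pair is ordered by both measures.
#' @slot pearson Pearson correlation; NA if either sequence is constant.
#' @slot meanRatio mean elementwise ratio of the first to the second measure.
#' @slot ratioCI 95 percent Student bootstrap interval for the mean ratio.
#' @slot nBoot number of bootstrap replicates behind \code{ratioCI}.
#' @export
setClass("ComparisonReport",
         representation(nItems = "integer", discriminancy = "numeric",
                        consistency = "numeric", pearson = "numeric",
                        meanRatio = "numeric", ratioCI = "numeric",
                        nBoot = "integer"))

#' StudyReport class
#'
#' Result of a simulation or enumeration study: a per-matrix (or per-stratum)
#' table and a summary [ComparisonReport-class].
#'
#' @slot table data.frame of per-matrix measures (multiclass relation study)
#'   or per-total-size summaries (binary study).
#' @slot summary a [ComparisonReport-class].
#' @export
setClass("StudyReport",
         representation(table = "data.frame", summary = "ComparisonReport"))

setMethod("show", "ConfusionMatrix", function(object) {
  k <- nrow(object@counts)
  cat(sprintf("ConfusionMatrix: %d classes, total %s\n", k,
              format(sum(object@counts))))
  m <- object@counts
  dimnames(m) <- list(true = object@labels, predicted = object@labels)
  print(m)
})

setMethod("show", "ClassProfile", function(object) {
  cat(sprintf("ClassProfile for class %d: P_j = %.6g, CEN_j = %.6g\n",
              object@classIndex, object@pj, object@cenj))
})

setMethod("show", "MetricsReport", function(object) {
  cat(sprintf("MetricsReport (%d classes, total %s)\n", object@nClasses,
              format(object@total)))
  cat(sprintf("  ACC  = %.6g\n  MCC  = %.6g\n  CEN  = %.6g\n  tMCC = %s\n",
              object@acc, object@mcc, object@cen,
              if (is.na(object@tmcc)) "NA (outside transform domain)"
              else sprintf("%.6g", object@tmcc)))
})

setMethod("show", "ComparisonReport", function(object) {
  cat(sprintf("ComparisonReport over %d items\n", object@nItems))
  cat(sprintf("  discriminancy = %s\n",
              if (is.na(object@discriminancy)) "undefined" else format(object@discriminancy)))
  cat(sprintf("  consistency   = %s\n",
              if (is.na(object@consistency)) "undefined" else format(object@consistency)))
  cat(sprintf("  pearson       = %s\n",
              if (is.na(object@pearson)) "undefined" else format(object@pearson)))
  cat(sprintf("  mean ratio    = %s  (95%% CI %s, %s; %d bootstrap reps)\n",
              format(object@meanRatio), format(object@ratioCI[1]),
              format(object@ratioCI[2]), object@nBoot))
})

setMethod("show", "StudyReport", function(object) {
  cat(sprintf("StudyReport: %d table rows\n", nrow(object@table)))
  show(object@summary)
})
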