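#' Accuracy of a confusion matrix
#'
#' Fraction of correctly classified samples: the trace divided by the total.
#'
#' @param x a [ConfusionMatrix-class] or a square numeric matrix
#'   (rows = true class, columns = predicted class).
#' @return a number in [0, 1].
#' @examples
#' accuracy(matrix(c(2, 1, 1, 2), 2))
#' @export
setGeneric("accuracy", function(x) standardGeneric("accuracy"))

#' Multiclass Matthews Correlation Coefficient
#'
#' Correlation between the indicator encodings of true and predicted labels,
#' computed from the confusion matrix in closed form. Ranges over [-1, 1]:
#' 1 for perfect classification, 0 for no-information classifiers (all
#' samples assigned to one class, or a constant matrix). When the denominator
#' vanishes (a single non-zero row or column, or a constant matrix) the value
#' is 0 by convention.
#'
#' @inheritParams accuracy
#' @return a number in [-1, 1].
#' @examples
#' mcc(matrix(c(5, 1, 1, 1, 5, 1, 1, 1, 5), 3))  # 4/7
#' @export
setGeneric("mcc", function(x) standardGeneric("mcc"))

#' Confusion Entropy
#'
#' Entropy-based misclassification measure: a weighted sum over classes of
#' the entropy of the per-class misclassification probabilities, with
#' logarithm base 2(k - 1) and the convention 0 log 0 = 0. Zero exactly for
#' diagonal (perfect) matrices; at most 1 for k >= 3 classes, but it can
#' exceed 1 in the binary case.
#'
#' @inheritParams accuracy
#' @return a non-negative number.
#' @examples
#' cen(matrix(1, 4, 4))  # (3/4) log_6 8
#' @export
setGeneric("cen", function(x) standardGeneric("cen"))

#' Per-class Confusion Entropy profile
#'
#' The ingredients of [cen()] for one class: its confusion probability, the
#' misclassification probability vectors, and the per-class entropy. Classes
#' with zero row-plus-column mass have zero confusion probability and zero
#' entropy.
#'
#' @inheritParams accuracy
#' @param j 1-based class index.
#' @return a [ClassProfile-class].
#' @export
setGeneric("classProfile", function(x, j) standardGeneric("classProfile"))

#' All scalar measures of a confusion matrix
#'
#' Computes accuracy, MCC, CEN and the transformed MCC in one call. The
#' tMCC slot is NA when the MCC value lies outside the transform's domain
#' (see [tmcc()]).
#'
#' @inheritParams accuracy
#' @return a [MetricsReport-class].
#' @export
setGeneric("metricsReport", function(x) standardGeneric("metricsReport"))
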