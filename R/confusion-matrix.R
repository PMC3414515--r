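#' Construct a ConfusionMatrix
#'
#' @param counts square numeric matrix with non-negative entries and positive
#'   sum; rows index the true class, columns the predicted class.
#' @param labels optional character vector of class identifiers; defaults to
#'   the matrix dimnames when present, otherwise \code{"C1"..."Ck"}.
#' @return a validated [ConfusionMatrix-class].
#' @examples
#' confusionMatrix(matrix(c(5, 1, 1, 1, 5, 1, 1, 1, 5), 3))
#' @export
confusionMatrix <- function(counts, labels = NULL) {
  if (!is.matrix(counts) || !is.numeric(counts))
    inputError("counts must be a numeric matrix")
  if (is.null(labels)) {
    labels <- rownames(counts)
    if (is.null(labels)) labels <- paste0("C", seq_len(nrow(counts)))
  }
  counts <- unname(counts)
  storage.mode(counts) <- "double"
  labels <- as.character(labels)
  # surface validity failures as classed input errors
  tryCatch(new("ConfusionMatrix", counts = counts, labels = labels),
           error = function(e)
             inputError(paste("invalid confusion matrix:",
                              conditionMessage(e))))
}

#' @describeIn confusionMatrix the raw count matrix.
#' @param x a ConfusionMatrix.
#' @export
counts <- function(x) x@counts

#' @describeIn confusionMatrix the ordered class labels.
#' @export
classLabels <- function(x) x@labels

#' @describeIn confusionMatrix the number of classes k.
#' @export
nClasses <- function(x) nrow(x@counts)

#' @describeIn confusionMatrix the sum of all entries.
#' @export
totalCount <- function(x) sum(x@counts)

# coerce matrix-or-ConfusionMatrix input to a bare validated matrix
.asCountMatrix <- function(x) {
  if (is(x, "ConfusionMatrix")) return(x@counts)
  m <- unname(as.matrix(x))
  if (!is.numeric(m)) inputError("confusion matrix entries must be numeric")
  if (nrow(m) != ncol(m)) inputError("confusion matrix must be square")
  if (any(!is.finite(m)) || any(m < 0))
    inputError("confusion matrix entries must be finite and non-negative")
  if (sum(m) <= 0) inputError("confusion matrix total must be positive")
  m
}

#' Build a confusion matrix from paired label sequences
#'
#' Entry (i, j) counts the samples whose true class is the i-th class and
#' whose predicted class is the j-th. Classes are ordered by first appearance
#' (scanning each sample's true label then its predicted label) unless an
#' explicit \code{classOrder} is supplied.
#'
#' @param trueLabels,predictedLabels equal-length vectors of class labels.
#' @param classOrder optional character vector fixing the class order; every
#'   observed label must appear in it.
#' @return a [ConfusionMatrix-class].
#' @examples
#' confusionFromLabels(c("a", "a", "b"), c("a", "b", "b"))
#' @export
confusionFromLabels <- function(trueLabels, predictedLabels, classOrder = NULL) {
  if (length(trueLabels) != length(predictedLabels))
    inputError("true and predicted label sequences must have equal length")
  if (length(trueLabels) < 1L) inputError("label sequences must be non-empty")
  tl <- as.character(trueLabels)
  pl <- as.character(predictedLabels)
  if (is.null(classOrder)) {
    classOrder <- unique(as.vector(rbind(tl, pl)))
  } else {
    classOrder <- as.character(classOrder)
    missing <- setdiff(unique(c(tl, pl)), classOrder)
    if (length(missing) > 0)
      inputError(paste("labels absent from classOrder:",
                       paste(missing, collapse = ", ")))
  }
  if (length(classOrder) < 2L)
    inputError("at least 2 distinct classes are required")
  tf <- factor(tl, levels = classOrder)
  pf <- factor(pl, levels = classOrder)
  m <- unclass(table(tf, pf))
  confusionMatrix(matrix(as.numeric(m), nrow = length(classOrder)),
                  labels = classOrder)
}
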