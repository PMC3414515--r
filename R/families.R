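# Limit-case matrix families with closed-form measure values. The closed
# forms are implemented independently of the generic measures so that each
# route can oracle-check the other.

.checkK <- function(k, min = 2L) {
  k <- as.integer(k)
  if (is.na(k) || k < min) inputError(sprintf("k must be an integer >= %d", min))
  k
}

#' Uniform off-diagonal (diagonal-plus-constant) family
#'
#' The k x k matrix with every diagonal entry equal to \code{diag} and every
#' off-diagonal entry equal to \code{offdiag}. On this family the tMCC
#' transform reproduces CEN exactly, which makes it the analytic anchor of
#' the CEN-MCC relation.
#'
#' @param k number of classes (k >= 2).
#' @param diag positive diagonal value N.
#' @param offdiag non-negative off-diagonal value n.
#' @return \code{makeUniformOffdiag}: a [ConfusionMatrix-class];
#'   \code{uniformOffdiagMcc}, \code{uniformOffdiagCen}: closed-form measure
#'   values.
#' @examples
#' uniformOffdiagMcc(3, 5, 1)  # 4/7
#' @export
makeUniformOffdiag <- function(k, diag, offdiag) {
  k <- .checkK(k)
  if (!is.finite(diag) || diag <= 0) inputError("diag must be positive")
  if (!is.finite(offdiag) || offdiag < 0) inputError("offdiag must be non-negative")
  m <- matrix(offdiag, k, k)
  diag(m) <- diag
  confusionMatrix(m)
}

#' @rdname makeUniformOffdiag
#' @export
uniformOffdiagMcc <- function(k, diag, offdiag) {
  k <- .checkK(k)
  (diag - offdiag) / (diag + (k - 1) * offdiag)
}

#' @rdname makeUniformOffdiag
#' @export
uniformOffdiagCen <- function(k, diag, offdiag) {
  k <- .checkK(k)
  if (offdiag == 0) return(0)
  r <- diag + (k - 1) * offdiag
  (k - 1) * (offdiag / r) * log(2 * r / offdiag) / log(2 * (k - 1))
}

#' Single off-diagonal corner family
#'
#' The k x k all-ones matrix whose lower-left corner entry (last row, first
#' column) is a weight w >= 1. As w grows the accuracy k/(k^2 - 1 + w) and
#' the MCC decrease monotonically (MCC towards -1/(2(k-1))), while CEN
#' decreases towards 0 - the regime where low entropy coexists with poor
#' classification.
#'
#' @param k number of classes (k >= 2).
#' @param w positive corner weight.
#' @return \code{makeSingleCorner}: a [ConfusionMatrix-class];
#'   \code{singleCornerMetrics}: a [MetricsReport-class] from the closed
#'   forms; \code{singleCornerMccLimit}: the large-w MCC limit.
#' @export
makeSingleCorner <- function(k, w) {
  k <- .checkK(k)
  if (!is.finite(w) || w < 1) inputError("w must be >= 1")
  m <- matrix(1, k, k)
  m[k, 1] <- w
  confusionMatrix(m)
}

#' @rdname makeSingleCorner
#' @export
singleCornerMetrics <- function(k, w) {
  k <- .checkK(k)
  if (!is.finite(w) || w < 1) inputError("w must be >= 1")
  S <- k^2 - 1 + w
  acc <- k / S
  den <- S^2 - ((k - 1 + w)^2 + (k - 1) * k^2)
  mccVal <- if (den <= 0) 0 else k * (1 - w) / den
  # CEN: classes 1 and k share the corner mass, middle classes are uniform
  b <- 2 * (k - 1)
  d0 <- 2 * k - 1 + w
  h <- function(p) if (p > 0) -p * log(p) / log(b) else 0
  cen0 <- (2 * k - 3) * h(1 / d0) + h(w / d0)
  cenVal <- 2 * (d0 / (2 * S)) * cen0
  if (k > 2) {
    cenMid <- ((k - 1) / k) * log(2 * k) / log(b)
    cenVal <- cenVal + (k - 2) * (k / S) * cenMid
  }
  tmccVal <- if (mccVal >= -1 / (k - 1)) tmcc(mccVal, k) else NA_real_
  new("MetricsReport", acc = acc, mcc = mccVal, cen = cenVal,
      tmcc = tmccVal, nClasses = k, total = S)
}

#' @rdname makeSingleCorner
#' @export
singleCornerMccLimit <- function(k) {
  k <- .checkK(k)
  -1 / (2 * (k - 1))
}

#' Dice-rolling (no-information) family
#'
#' The k x k all-ones matrix whose last row is a constant m > 0: the
#' confusion matrix of a classifier whose predictions are independent of the
#' true class, on classes unbalanced by the factor m. MCC is identically 0
#' on this family, while CEN varies with m (decreasing, with large-m limit
#' \code{diceCenLimit(k)}) - no-information classifiers have a single MCC
#' value but a whole spectrum of CEN values.
#'
#' @param k number of classes (k >= 2).
#' @param m positive last-row weight.
#' @return \code{makeDice}: a [ConfusionMatrix-class]; \code{diceMetrics}: a
#'   [MetricsReport-class] from the closed forms; \code{diceCenLimit}: the
#'   large-m CEN limit, an increasing function of k with asymptote 1/2.
#' @export
makeDice <- function(k, m) {
  k <- .checkK(k)
  if (!is.finite(m) || m <= 0) inputError("m must be positive")
  mat <- matrix(1, k, k)
  mat[k, ] <- m
  confusionMatrix(mat)
}

#' @rdname makeSingleCorner
#' @export
diceMetrics <- function(k, m) {
  k <- .checkK(k)
  if (!is.finite(m) || m <= 0) inputError("m must be positive")
  S <- k * (k - 1 + m)
  acc <- (k - 1 + m) / S
  b <- 2 * (k - 1)
  h <- function(p) ifelse(p > 0, -p * log(p) / log(b), 0)
  dn <- 2 * k - 1 + m            # row-plus-column mass, classes 1..k-1
  dl <- (k + 1) * m + k - 1      # last class
  cenN <- (2 * k - 3) * h(1 / dn) + h(m / dn)
  cenL <- (k - 1) * (h(m / dl) + h(1 / dl))
  cenVal <- (k - 1) * (dn / (2 * S)) * cenN + (dl / (2 * S)) * cenL
  new("MetricsReport", acc = acc, mcc = 0, cen = cenVal,
      tmcc = tmcc(0, k), nClasses = k, total = S)
}

#' @rdname makeSingleCorner
#' @export
diceCenLimit <- function(k) {
  k <- .checkK(k)
  ((k - 1) / (2 * k)) * log(k + 1) / log(2 * (k - 1))
}
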