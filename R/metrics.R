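# x * log(x) with the 0 log 0 = 0 convention, implemented by skipping zero
# terms (no epsilon regularisation)
.entropyTerm <- function(p, logBase) {
  out <- numeric(length(p))
  pos <- p > 0
  out[pos] <- -p[pos] * log(p[pos]) / log(logBase)
  out
}

.accMatrix <- function(m) sum(diag(m)) / sum(m)

# multiclass MCC closed form from row sums, column sums and the trace
.mccMatrix <- function(m) {
  S <- sum(m)
  rs <- rowSums(m)
  cs <- colSums(m)
  num <- S * sum(diag(m)) - sum(rs * cs)
  d1 <- S^2 - sum(cs^2)
  d2 <- S^2 - sum(rs^2)
  if (d1 <= 0 || d2 <= 0) return(0)
  num / (sqrt(d1) * sqrt(d2))
}

# CEN, vectorised over the matrix. d_j is the row-plus-column mass of class
# j (the diagonal entry counted twice); classes with d_j = 0 are skipped.
.cenMatrix <- function(m) {
  k <- nrow(m)
  if (k < 2L) inputError("CEN requires at least 2 classes")
  S <- sum(m)
  d <- rowSums(m) + colSums(m)
  b <- 2 * (k - 1)
  dSafe <- ifelse(d == 0, 1, d)
  rowP <- m / dSafe            # row j scaled by d_j
  colP <- t(t(m) / dSafe)      # column j scaled by d_j
  hr <- .entropyTerm(rowP, b)
  hc <- .entropyTerm(colP, b)
  dim(hr) <- dim(hc) <- dim(m)
  cenj <- rowSums(hr) - diag(hr) + colSums(hc) - diag(hc)
  sum(ifelse(d == 0, 0, d / (2 * S) * cenj))
}

.classProfileMatrix <- function(m, j) {
  k <- nrow(m)
  j <- as.integer(j)
  if (is.na(j) || j < 1L || j > k) inputError("class index out of range")
  S <- sum(m)
  d <- sum(m[j, ]) + sum(m[, j])
  b <- 2 * (k - 1)
  if (d == 0) {
    zero <- numeric(k - 1L)
    return(new("ClassProfile", classIndex = j, pj = 0,
               pTrueToPred = zero, pPredFromTrue = zero, cenj = 0))
  }
  pTrueToPred <- m[j, -j] / d
  pPredFromTrue <- m[-j, j] / d
  cenj <- sum(.entropyTerm(pTrueToPred, b)) + sum(.entropyTerm(pPredFromTrue, b))
  new("ClassProfile", classIndex = j, pj = d / (2 * S),
      pTrueToPred = unname(pTrueToPred), pPredFromTrue = unname(pPredFromTrue),
      cenj = cenj)
}

#' @rdname accuracy
#' @export
setMethod("accuracy", "ConfusionMatrix", function(x) .accMatrix(x@counts))

#' @rdname accuracy
#' @export
setMethod("accuracy", "matrix", function(x) .accMatrix(.asCountMatrix(x)))

#' @rdname mcc
#' @export
setMethod("mcc", "ConfusionMatrix", function(x) .mccMatrix(x@counts))

#' @rdname mcc
#' @export
setMethod("mcc", "matrix", function(x) .mccMatrix(.asCountMatrix(x)))

#' @rdname cen
#' @export
setMethod("cen", "ConfusionMatrix", function(x) .cenMatrix(x@counts))

#' @rdname cen
#' @export
setMethod("cen", "matrix", function(x) .cenMatrix(.asCountMatrix(x)))

#' @rdname classProfile
#' @export
setMethod("classProfile", "ConfusionMatrix",
          function(x, j) .classProfileMatrix(x@counts, j))

#' @rdname classProfile
#' @export
setMethod("classProfile", "matrix",
          function(x, j) .classProfileMatrix(.asCountMatrix(x), j))

#' Transformed MCC
#'
#' The logarithmic transform of the Matthews Correlation Coefficient that
#' approximates the Confusion Entropy:
#' \deqn{tMCC = \frac{k-1}{k}\,(1 - MCC)\,\log_{2(k-1)}\frac{2k}{1 - MCC}.}
#' On uniform off-diagonal (diagonal-plus-constant) matrices the transform
#' reproduces CEN exactly; on general matrices it is a tight approximation.
#' Its domain is \eqn{-1/(k-1) \le MCC \le 1}, on which it decreases from 1
#' (complete balanced misclassification) to 0 (perfect classification).
#'
#' @param mccValue numeric vector of MCC values.
#' @param k number of classes (k >= 2).
#' @param policy what to do with values outside the domain: \code{"error"}
#'   (default) raises a domain error; \code{"clamp"} evaluates at the nearest
#'   domain boundary.
#' @return numeric vector of non-negative transform values.
#' @examples
#' tmcc(4 / 7, 3)  # equals cen() of the 3x3 matrix with diagonal 5, off-diagonal 1
#' @export
tmcc <- function(mccValue, k, policy = c("error", "clamp")) {
  policy <- match.arg(policy)
  k <- as.integer(k)
  if (is.na(k) || k < 2L) inputError("k must be an integer >= 2")
  if (any(!is.finite(mccValue))) inputError("mccValue must be finite")
  lo <- -1 / (k - 1)
  out <- numeric(length(mccValue))
  bad <- mccValue < lo | mccValue > 1
  if (any(bad)) {
    if (policy == "error")
      domainError(sprintf(
        "MCC value outside the tMCC domain [%.6g, 1] for k = %d", lo, k))
    mccValue <- pmin(1, pmax(lo, mccValue))
  }
  at1 <- mccValue >= 1
  m <- mccValue[!at1]
  out[!at1] <- ((k - 1) / k) * (1 - m) * log(2 * k / (1 - m)) / log(2 * (k - 1))
  out
}

#' Dimension-scaled Confusion Entropy
#'
#' The rescaling \eqn{k/(k-1)\, CEN} used when relating CEN to the
#' transformed MCC across matrices of different dimension.
#'
#' @inheritParams accuracy
#' @return a non-negative number.
#' @export
scaledCen <- function(x) {
  m <- .asCountMatrix(x)
  k <- nrow(m)
  k / (k - 1) * .cenMatrix(m)
}

.metricsReportMatrix <- function(m) {
  k <- nrow(m)
  mccVal <- .mccMatrix(m)
  tmccVal <- if (mccVal >= -1 / (k - 1) && mccVal <= 1)
    tmcc(mccVal, k) else NA_real_
  new("MetricsReport", acc = .accMatrix(m), mcc = mccVal,
      cen = .cenMatrix(m), tmcc = tmccVal, nClasses = as.integer(k),
      total = sum(m))
}

#' @rdname metricsReport
#' @export
setMethod("metricsReport", "ConfusionMatrix",
          function(x) .metricsReportMatrix(x@counts))

#' @rdname metricsReport
#' @export
setMethod("metricsReport", "matrix",
          function(x) .metricsReportMatrix(.asCountMatrix(x)))

#' Binary classification measures from the four counts
#'
#' Convenience wrapper for two-class problems. The confusion matrix is
#' \code{rbind(c(tp, fn), c(fp, tn))} (rows = true class, columns =
#' predicted class, positives first). MCC reduces to its familiar four-term
#' form; CEN uses logarithm base 2 and, unlike the multiclass case, can
#' exceed 1: for matrices \code{rbind(c(t, n), c(n, 0))} this happens
#' exactly when t/n < 1.
#'
#' @param tp,fn,fp,tn non-negative counts (true positives, false negatives,
#'   false positives, true negatives) with a positive sum.
#' @return a [MetricsReport-class].
#' @examples
#' binaryMetrics(1, 2, 2, 0)  # CEN above 1
#' @export
binaryMetrics <- function(tp, fn, fp, tn) {
  v <- c(tp, fn, fp, tn)
  if (length(v) != 4L || any(!is.finite(v)) || any(v < 0))
    inputError("tp, fn, fp, tn must be single non-negative numbers")
  if (sum(v) <= 0) inputError("at least one count must be positive")
  num <- tp * tn - fp * fn
  den <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  mccVal <- if (den <= 0) 0 else num / sqrt(den)
  m <- rbind(c(tp, fn), c(fp, tn))
  cenVal <- .cenMatrix(m)
  tmccVal <- if (mccVal >= -1) tmcc(mccVal, 2L) else NA_real_
  new("MetricsReport", acc = .accMatrix(m), mcc = mccVal, cen = cenVal,
      tmcc = tmccVal, nClasses = 2L, total = sum(v))
}
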