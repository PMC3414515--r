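test_that("accuracy is trace over total", {
  expect_equal(accuracy(diag(c(3, 4, 5))), 1)
  expect_equal(accuracy(rbind(c(0, 2), c(3, 0))), 0)
  expect_equal(accuracy(rbind(c(2, 1), c(1, 2))), 4 / 6)
  expect_error(accuracy(matrix(0, 2, 2)), class = "mccen_input_error")
})

test_that("multiclass MCC handles perfect, constant and anti-diagonal cases", {
  expect_equal(mcc(diag(3)), 1)
  expect_equal(mcc(matrix(1, 4, 4)), 0)
  expect_equal(mcc(rbind(c(0, 5), c(5, 0))), -1)
  expect_equal(mcc(counts(makeUniformOffdiag(3, 5, 1))), 4 / 7)
  # degenerate denominators: one nonzero column / one nonzero row
  expect_equal(mcc(rbind(c(3, 0), c(7, 0))), 0)
  expect_equal(mcc(rbind(c(0, 0), c(3, 7))), 0)
})

test_that("MCC equals the indicator-matrix covariance definition", {
  set.seed(101)
  for (rep in 1:100) {
    k <- sample(2:6, 1)
    m <- randIntMatrix(k)
    expect_equal(mcc(m), mccIndicatorOracle(m), tolerance = 1e-10)
  }
})

test_that("class profiles match the probability definitions", {
  p <- classProfile(matrix(1, 3, 3), 2)
  expect_equal(p@pj, 1 / 3)

  pd <- classProfile(diag(c(2, 3, 4)), 1)
  expect_equal(pd@pTrueToPred, c(0, 0))
  expect_equal(pd@pPredFromTrue, c(0, 0))
  expect_equal(pd@cenj, 0)

  pb <- classProfile(rbind(c(1, 2), c(2, 0)), 1)
  expect_equal(pb@pj, 0.6)
  expect_equal(pb@pTrueToPred, 1 / 3)
  expect_equal(pb@pPredFromTrue, 1 / 3)

  # a class with zero row and column mass contributes nothing
  pz <- classProfile(rbind(c(0, 0, 0), c(0, 2, 1), c(0, 1, 2)), 1)
  expect_equal(pz@pj, 0)
  expect_equal(pz@cenj, 0)

  expect_error(classProfile(diag(3), 4), class = "mccen_input_error")
  expect_error(classProfile(diag(3), 0), class = "mccen_input_error")
})

test_that("confusion probabilities sum to one", {
  set.seed(7)
  for (rep in 1:50) {
    k <- sample(2:6, 1)
    m <- randIntMatrix(k)
    pj <- vapply(seq_len(k), function(j) classProfile(m, j)@pj, 0)
    expect_equal(sum(pj), 1, tolerance = 1e-12)
  }
})

test_that("CEN reproduces the anchor values", {
  expect_equal(cen(diag(c(1, 7, 2))), 0)
  z <- matrix(1, 3, 3); diag(z) <- 0
  expect_equal(cen(z), 1, tolerance = 1e-14)
  expect_equal(cen(matrix(1, 4, 4)), (3 / 4) * log(8, base = 6),
               tolerance = 1e-14)
  expect_equal(cen(rbind(c(1, 2), c(2, 0))), 0.4 * (1 + log2(3)),
               tolerance = 1e-14)
  expect_error(cen(matrix(5, 1, 1)), class = "mccen_input_error")
})

test_that("CEN agrees with the definitional oracle on random matrices", {
  set.seed(202)
  for (rep in 1:100) {
    k <- sample(2:6, 1)
    m <- randIntMatrix(k)
    expect_equal(cen(m), cenOracle(m), tolerance = 1e-12)
  }
})

test_that("MCC and CEN are scale invariant and permutation equivariant", {
  set.seed(303)
  for (rep in 1:40) {
    k <- sample(2:6, 1)
    m <- randIntMatrix(k)
    cc <- runif(1, 0.01, 100)
    expect_equal(mcc(cc * m), mcc(m), tolerance = 1e-10)
    expect_equal(cen(cc * m), cen(m), tolerance = 1e-10)
    p <- sample(k)
    expect_equal(accuracy(m[p, p]), accuracy(m), tolerance = 1e-12)
    expect_equal(mcc(m[p, p]), mcc(m), tolerance = 1e-10)
    expect_equal(cen(m[p, p]), cen(m), tolerance = 1e-10)
  }
})

test_that("measure ranges hold on random sweeps", {
  set.seed(404)
  for (rep in 1:150) {
    k <- sample(2:7, 1)
    m <- randIntMatrix(k)
    v <- mcc(m)
    expect_true(v >= -1 - 1e-12 && v <= 1 + 1e-12)
    cv <- cen(m)
    expect_true(cv >= 0)
    if (k >= 3) expect_true(cv <= 1 + 1e-12)
  }
})

test_that("tMCC is zero at perfect classification and exact on the family", {
  expect_equal(tmcc(1, 3), 0)
  expect_equal(tmcc(1, 17), 0)
  m <- makeUniformOffdiag(3, 5, 1)
  expect_equal(tmcc(mcc(m), 3), cen(m), tolerance = 1e-15)
  # complete balanced misclassification maps to CEN = 1
  expect_equal(tmcc(-1 / 2, 3), 1, tolerance = 1e-14)
})

test_that("tMCC domain policy errors or clamps", {
  expect_error(tmcc(-0.9, 3), class = "mccen_domain_error")
  expect_equal(tmcc(-0.9, 3, policy = "clamp"), tmcc(-0.5, 3))
  expect_equal(tmcc(c(0.2, 1), 4), c(tmcc(0.2, 4), 0))
  expect_error(tmcc(0.5, 1), class = "mccen_input_error")
})

test_that("binary metrics agree with the generic measures on the 2x2 matrix", {
  r <- binaryMetrics(5, 0, 0, 5)
  expect_equal(r@mcc, 1)
  expect_equal(r@cen, 0)

  r2 <- binaryMetrics(1, 1, 1, 1)
  expect_equal(r2@mcc, 0)
  expect_equal(r2@cen, 1)

  r3 <- binaryMetrics(1, 2, 2, 0)
  expect_equal(r3@cen, 0.4 * (1 + log2(3)), tolerance = 1e-14)
  expect_true(r3@cen > 1)

  set.seed(505)
  for (rep in 1:60) {
    v <- sample(0:15, 4, replace = TRUE)
    if (sum(v) == 0) v[1] <- 1
    m <- rbind(v[1:2], v[3:4])
    r <- binaryMetrics(v[1], v[2], v[3], v[4])
    expect_equal(r@mcc, mcc(m), tolerance = 1e-12)
    expect_equal(r@cen, cen(m), tolerance = 1e-12)
    expect_equal(r@acc, accuracy(m), tolerance = 1e-12)
  }
  expect_error(binaryMetrics(0, 0, 0, 0), class = "mccen_input_error")
})

test_that("metricsReport bundles the four measures consistently", {
  m <- makeUniformOffdiag(4, 9, 2)
  r <- metricsReport(m)
  expect_equal(r@acc, accuracy(m))
  expect_equal(r@mcc, mcc(m))
  expect_equal(r@cen, cen(m))
  expect_equal(r@tmcc, tmcc(r@mcc, 4))
  expect_equal(r@nClasses, 4L)
  # outside the transform domain the report carries NA rather than an error
  strongNeg <- rbind(c(0, 5, 0), c(5, 0, 0), c(0, 0, 1))  # MCC = -4/7 < -1/2
  expect_true(mcc(strongNeg) < -1 / 2)
  expect_true(is.na(metricsReport(strongNeg)@tmcc))
  # the binary domain covers all of [-1, 1]: total misclassification maps to 1
  expect_equal(metricsReport(rbind(c(0, 5), c(5, 0)))@tmcc, 1)
})
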