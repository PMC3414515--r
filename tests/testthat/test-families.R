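test_that("family constructors build the stated matrices", {
  expect_equal(counts(makeUniformOffdiag(3, 5, 1)),
               rbind(c(5, 1, 1), c(1, 5, 1), c(1, 1, 5)))
  expect_equal(counts(makeUniformOffdiag(2, 1, 1)), matrix(1, 2, 2))
  expect_equal(counts(makeUniformOffdiag(4, 7, 0)), diag(c(7, 7, 7, 7)))

  expect_equal(counts(makeSingleCorner(2, 3)), rbind(c(1, 1), c(3, 1)))
  expect_equal(counts(makeSingleCorner(3, 1)), matrix(1, 3, 3))
  expect_equal(counts(makeSingleCorner(3, 10)),
               rbind(c(1, 1, 1), c(1, 1, 1), c(10, 1, 1)))

  expect_equal(counts(makeDice(3, 2)),
               rbind(c(1, 1, 1), c(1, 1, 1), c(2, 2, 2)))
  expect_equal(counts(makeDice(2, 1)), matrix(1, 2, 2))
  expect_equal(counts(makeDice(4, 0.5))[4, ], rep(0.5, 4))
})

test_that("uniform off-diagonal closed forms match the generic measures", {
  expect_equal(uniformOffdiagMcc(3, 5, 1), 4 / 7)
  expect_equal(uniformOffdiagMcc(5, 9, 9), 0)
  expect_equal(uniformOffdiagMcc(4, 3, 0), 1)
  expect_equal(uniformOffdiagCen(6, 8, 0), 0)
  expect_equal(uniformOffdiagCen(4, 1, 1), (3 / 4) * log(8, base = 6),
               tolerance = 1e-14)

  for (k in 2:8) for (N in c(1, 2, 7, 50)) for (n in c(0, 1, 3, 50)) {
    m <- makeUniformOffdiag(k, N, n)
    expect_equal(uniformOffdiagMcc(k, N, n), mcc(m), tolerance = 1e-12)
    expect_equal(uniformOffdiagCen(k, N, n), cen(m), tolerance = 1e-10)
    # the transform identity is exact on this family
    expect_equal(tmcc(uniformOffdiagMcc(k, N, n), k),
                 uniformOffdiagCen(k, N, n), tolerance = 1e-12)
  }
})

test_that("single-corner closed forms match the generic measures", {
  expect_equal(singleCornerMetrics(3, 1)@mcc, 0)
  for (k in 2:8) for (w in c(1, 2, 5, 17, 50)) {
    m <- makeSingleCorner(k, w)
    r <- singleCornerMetrics(k, w)
    expect_equal(r@acc, k / (k^2 - 1 + w), tolerance = 1e-14)
    expect_equal(r@acc, accuracy(m), tolerance = 1e-12)
    expect_equal(r@mcc, mcc(m), tolerance = 1e-10)
    expect_equal(r@cen, cen(m), tolerance = 1e-10)
  }
})

test_that("single-corner measures decrease monotonically in the corner weight", {
  for (k in c(3, 5)) {
    ws <- c(1, 2, 5, 10, 50, 200, 1000)
    reps <- lapply(ws, function(w) singleCornerMetrics(k, w))
    accs <- vapply(reps, function(r) r@acc, 0)
    mccs <- vapply(reps, function(r) r@mcc, 0)
    cens <- vapply(reps, function(r) r@cen, 0)
    expect_true(all(diff(accs) < 0))
    expect_true(all(diff(mccs) < 0))
    expect_true(all(diff(cens) < 0))
  }
})

test_that("single-corner asymptotics: ACC and CEN vanish, MCC reaches its limit", {
  for (k in c(2, 3, 6)) {
    r <- singleCornerMetrics(k, 1e6)
    expect_lt(r@acc, 1e-3)
    expect_lt(r@cen, 1e-3)
    expect_equal(r@mcc, singleCornerMccLimit(k), tolerance = 1e-3)
    expect_equal(r@mcc, mcc(makeSingleCorner(k, 1e6)), tolerance = 1e-10)
  }
  expect_equal(singleCornerMccLimit(3), -1 / 4)
})

test_that("dice family has identically zero MCC and varying CEN", {
  set.seed(606)
  for (rep in 1:1000) {
    k <- sample(2:10, 1)
    m <- runif(1, 0.05, 50)
    r <- diceMetrics(k, m)
    expect_identical(r@mcc, 0)
    expect_equal(mcc(makeDice(k, m)), 0, tolerance = 1e-12)
  }
  # degenerate case: m = 1 is the constant matrix
  expect_equal(diceMetrics(3, 1)@cen, cen(matrix(1, 3, 3)), tolerance = 1e-14)
  # CEN strictly decreases as the imbalance grows
  cens <- vapply(c(1, 2, 4, 8), function(m) diceMetrics(3, m)@cen, 0)
  expect_true(all(diff(cens) < 0))
})

test_that("dice closed-form CEN matches the generic measure on a grid", {
  for (k in 2:8) for (m in c(0.25, 1, 2, 7.5, 50)) {
    expect_equal(diceMetrics(k, m)@cen, cen(makeDice(k, m)), tolerance = 1e-10)
  }
})

test_that("dice large-m CEN limit is attained and increases with k", {
  for (k in c(2, 3, 5, 9)) {
    expect_equal(diceMetrics(k, 1e6)@cen, diceCenLimit(k), tolerance = 1e-3)
  }
  # increasing towards 1/2 across the multiclass range (the binary case,
  # with its smaller logarithm base, sits above the k = 3 value)
  lims <- vapply(3:40, diceCenLimit, 0)
  expect_true(all(diff(lims) > 0))
  expect_true(all(lims < 0.5))
})
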