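test_that("transition estimation returns row proportions", {
  counts <- rbind(c(10, 10, 0, 0),
                  c(0, 5, 0, 0),
                  c(0, 0, 5, 0),
                  c(0, 0, 0, 5))
  P <- estimateTransitionMatrix(panelFromCounts(counts), horizon = 3)
  expect_equal(probs(P)[1, ], c(healthy = 0.5, mild = 0.5, moderate = 0,
                                severe = 0))
  expect_equal(horizon(P), 3)
  # everyone retains their state -> identity
  Pid <- estimateTransitionMatrix(panelFromCounts(diag(4) * 5), horizon = 3)
  expect_equal(unname(probs(Pid)), diag(4))
})

test_that("an unobserved origin state errors unless a prior row is given", {
  pan <- panelFromCounts(rbind(c(5, 0, 0, 0), c(0, 5, 0, 0),
                               c(0, 0, 5, 0), c(0, 0, 0, 0)))
  expect_error(estimateTransitionMatrix(pan), "origin state 4")
  P <- estimateTransitionMatrix(pan, priorRows = diag(4))
  expect_equal(unname(probs(P)[4, ]), c(0, 0, 0, 1))
})

test_that("grouped estimation splits the panel and recovers per-group truths", {
  set.seed(7)
  truths <- list(ME = TransitionMatrix(randomStochastic(4), horizon = 3),
                 FE = TransitionMatrix(randomStochastic(4), horizon = 3))
  pan <- generatePanel(n = 10000, matrices = truths, groupBy = "sex",
                       seed = 7)
  fits <- estimateTransitionMatrix(pan, horizon = 3, by = "sex")
  expect_setequal(names(fits), c("ME", "FE"))
  for (g in names(fits))
    expect_lt(max(abs(probs(fits[[g]]) - probs(truths[[g]]))), 0.05)
})

test_that("estimation error shrinks with panel size", {
  truth <- annualDisabilityMatrix()
  err <- sapply(c(500, 5000), function(n) {
    pan <- generatePanel(n = n, matrices = truth, seed = 123)
    max(abs(probs(estimateTransitionMatrix(pan, horizon = 1)) -
              probs(truth)))
  })
  expect_lt(err[2], err[1])
})

test_that("step transform divides off-diagonals by the horizon", {
  I3 <- TransitionMatrix(diag(4), horizon = 3)
  expect_equal(unname(probs(naiveStepTransform(I3))), diag(4))
  # 2-state case: [[0.7, 0.3], [0.3, 0.7]] over 3 years -> [[0.9, 0.1], ...]
  P2 <- TransitionMatrix(matrix(c(0.7, 0.3, 0.3, 0.7), 2, 2, byrow = TRUE),
                         horizon = 3)
  Q <- probs(naiveStepTransform(P2))
  expect_equal(unname(Q), matrix(c(0.9, 0.1, 0.1, 0.9), 2, byrow = TRUE))
  # the cube only roughly recovers the input (diagnostic, not an identity)
  expect_lt(max(abs(Q %*% Q %*% Q - probs(P2))), 0.1)
  # pooled 3-year matrix, row 1: off-diagonals are the renormalized
  # printed entries divided by 3
  P3 <- eq3()
  row1raw <- c(0.3382, 0.5819, 0.0798, 0.0037)
  expected_off <- (row1raw / sum(row1raw) / 3)[2:4]
  got <- probs(naiveStepTransform(P3))[1, ]
  expect_equal(unname(got[2:4]), expected_off, tolerance = 1e-12)
  expect_equal(unname(got[1]), 1 - sum(expected_off), tolerance = 1e-12)
})

test_that("step transform matches an element-wise arithmetic oracle", {
  set.seed(99)
  for (rep in 1:20) {
    M <- randomStochastic(4)
    P1 <- probs(naiveStepTransform(TransitionMatrix(M, horizon = 3)))
    oracle <- matrix(NA_real_, 4, 4)
    for (i in 1:4) for (j in 1:4)
      oracle[i, j] <- if (i == j) 1 - sum(M[i, -i] / 3) else M[i, j] / 3
    expect_equal(unname(P1), oracle, tolerance = 1e-12)
  }
})

test_that("relative error is |actual - estimated| / actual", {
  expect_equal(relativeError(100, 100), 0)
  expect_equal(relativeError(100, 95), 0.05)
  expect_equal(relativeError(200, 210), 0.05)
  expect_error(relativeError(0, 1), "undefined")
})

test_that("calibration of the identity is the identity with zero error", {
  cal <- calibrateAnnualMatrix(TransitionMatrix(diag(4), horizon = 3),
                               rep(100, 4))
  expect_true(converged(cal))
  expect_equal(max(perStateError(cal)), 0, tolerance = 1e-9)
  expect_equal(unname(probs(annualMatrix(cal))), diag(4), tolerance = 1e-9)
})

test_that("calibration recovers count projections from a constructed cube", {
  set.seed(31)
  Q <- randomStochastic(4)
  P3 <- TransitionMatrix(Q %*% Q %*% Q, horizon = 3)
  counts <- c(400, 300, 200, 100)
  cal <- calibrateAnnualMatrix(P3, counts)
  expect_true(converged(cal))
  P1 <- probs(annualMatrix(cal))
  pred <- counts %*% P1 %*% P1 %*% P1
  actual <- counts %*% probs(P3)
  expect_true(all(relativeError(actual, pred) <= 0.05))
})

test_that("calibration never worsens the step-transform objective", {
  set.seed(57)
  for (rep in 1:5) {
    P3 <- TransitionMatrix(randomStochastic(4), horizon = 3)
    counts <- runif(4, 100, 1000)
    cal <- calibrateAnnualMatrix(P3, counts)
    expect_lte(max(perStateError(cal)), max(cal@naiveError) + 1e-12)
  }
})

test_that("calibration preserves structural zeros of the multi-year matrix", {
  cal <- calibrateAnnualMatrix(eq3(), rep(1000, 4))
  expect_identical(probs(annualMatrix(cal))[4, 1], 0)  # no severe -> healthy
})

test_that("shipped matrices satisfy stochasticity invariants", {
  # annual reference matrix: each row sums to 1 exactly as printed
  expect_equal(rowSums(probs(annualDisabilityMatrix())), rep(1, 4),
               tolerance = 1e-12, ignore_attr = TRUE)
  # 3-year matrix over-sums as printed and is renormalized with a warning
  expect_warning(P3 <- threeYearDisabilityMatrix(), "renormalizing 2 row")
  expect_equal(rowSums(probs(P3)), rep(1, 4), tolerance = 1e-12,
               ignore_attr = TRUE)
  # the raw printed values are exposed as a plain (non-stochastic) matrix
  raw <- threeYearDisabilityMatrix(renormalize = FALSE)
  expect_false(is(raw, "TransitionMatrix"))
  expect_equal(unname(rowSums(raw)), c(1.0036, 1.0036, 1, 1))
  # healthy -> mild over 3 years is the documented 58.19% (before rescaling)
  expect_equal(raw["healthy", "mild"], 0.5819)
})

test_that("every operation returns row-stochastic matrices", {
  set.seed(11)
  for (rep in 1:10) {
    P3 <- TransitionMatrix(randomStochastic(4), horizon = 3)
    for (M in list(probs(naiveStepTransform(P3)),
                   probs(annualMatrix(calibrateAnnualMatrix(
                     P3, runif(4, 50, 500)))))) {
      expect_true(all(M >= 0 & M <= 1 + 1e-12))
      expect_equal(rowSums(M), rep(1, 4), tolerance = 1e-9,
                   ignore_attr = TRUE)
    }
  }
})
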