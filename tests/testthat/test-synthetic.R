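test_that("panel generation follows the true matrix and fixed seed", {
  # identity truth: every subject retains its state
  pan <- generatePanel(n = 300, matrices = TransitionMatrix(diag(4),
                                                            horizon = 3),
                       seed = 1)
  expect_equal(pan$state1, pan$state0)
  expect_equal(pan$year1 - pan$year0, rep(3, 300))
  # bit-exact reproducibility under a fixed seed
  expect_identical(generatePanel(n = 100, seed = 9),
                   generatePanel(n = 100, seed = 9))
  expect_false(identical(generatePanel(n = 100, seed = 9)$state1,
                         generatePanel(n = 100, seed = 10)$state1))
})

test_that("a 5000-subject panel recovers the generating matrix within 0.05", {
  truth <- annualDisabilityMatrix()
  pan <- generatePanel(n = 5000, matrices = truth, seed = 13)
  Phat <- estimateTransitionMatrix(pan, horizon = 1)
  expect_lt(max(abs(probs(Phat) - probs(truth))), 0.05)
})

test_that("noise-free item responses round-trip through scoring", {
  set.seed(17)
  targets <- sample(1:4, 250, replace = TRUE)
  resp <- generateItemResponses(targets)
  out <- scoreSubjects(resp)
  expect_equal(out$state_code, targets)
  # maximal responses land in the healthy band
  allMax <- generateItemResponses(rep(1L, 5), seed = 2)
  expect_true(all(scoreSubjects(allMax)$state_code == 1L))
})

test_that("response noise misclassifies at the configured rate", {
  set.seed(23)
  targets <- sample(1:4, 1500, replace = TRUE)
  resp <- generateItemResponses(targets, noise = 0.1)
  out <- scoreSubjects(resp)
  mis <- mean(out$state_code != targets)
  # binomial 3-sigma band around 0.1 at n = 1500
  expect_lt(abs(mis - 0.1), 3 * sqrt(0.1 * 0.9 / 1500))
})

test_that("synthetic demography is internally consistent and growth-biased", {
  demo <- generateDemography(baseTotal = 8000)
  expect_equal(totalPersons(demo$frame), 8000)
  expect_true(all(demo$lifeTable >= 0 & demo$lifeTable <= 1))
  expect_true(all(demo$entrants >= 0))
  expect_setequal(names(demo$lifeTable), rownames(stateCounts(demo$frame)))
  # entrants exceed deaths each year: totals grow along the trajectory
  pr <- projectCohort(demo$frame, annualDisabilityMatrix(),
                      lifeTable = demo$lifeTable,
                      entrants = demo$entrants, years = 5)
  tot <- vapply(trajectory(pr), totalPersons, numeric(1))
  expect_true(all(diff(tot) > 0))
  # zero-mortality override gives a life table of zeros
  zero <- generateDemography(baseTotal = 100,
                             mortality = setNames(rep(0, 8),
                                                  names(demo$lifeTable)))
  expect_true(all(zero$lifeTable == 0))
})

test_that("microsimulation equals the deterministic engine in the 0/1 limit", {
  # deterministic dynamics: everyone worsens one state (severe absorbing),
  # no deaths, fixed entrants
  M <- matrix(0, 4, 4)
  M[cbind(1:3, 2:4)] <- 1; M[4, 4] <- 1
  dimnames(M) <- list(stateLabels(), stateLabels())
  f0 <- PopulationFrame(2025, c(100, 50, 25, 10))
  ms <- microsimOracle(f0, TransitionMatrix(M), entrants = c(all = 20),
                       years = 3, seed = 4)
  det <- as.data.frame(projectCohort(f0, TransitionMatrix(M),
                                     entrants = c(all = 20), years = 3))
  m <- merge(ms, det, by = c("year", "group", "state"))
  expect_equal(m$count.x, m$count.y, ignore_attr = TRUE)
})

test_that("two seeds give different realizations around the same expectation", {
  f0 <- PopulationFrame(2025, c(2000, 2000, 2000, 2000))
  M <- annualDisabilityMatrix()
  a <- microsimOracle(f0, M, lifeTable = c(all = 0.02), years = 2, seed = 1)
  b <- microsimOracle(f0, M, lifeTable = c(all = 0.02), years = 2, seed = 2)
  expect_false(identical(a$count, b$count))
  det <- as.data.frame(projectCohort(f0, M, lifeTable = c(all = 0.02),
                                     years = 2))
  for (x in list(a, b)) {
    m <- merge(x, det, by = c("year", "group", "state"))
    expect_true(all(abs(m$count.x - m$count.y) <=
                      3 * pmax(sqrt(m$count.y), 1)))
  }
})
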