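test_that("survival multiplies counts by one minus the mortality rate", {
  f <- PopulationFrame(2025, c(1000, 0, 0, 0))
  expect_equal(stateCounts(survive(f, c(all = 0)))[1, 1], 1000,
               ignore_attr = TRUE)
  expect_equal(stateCounts(survive(f, c(all = 0.01)))[1, 1], 990,
               ignore_attr = TRUE)
  # mixed groups against a per-group hand computation
  cnt <- rbind(DL = c(100, 50, 20, 10), HL = c(40, 30, 20, 10))
  colnames(cnt) <- stateLabels()
  g <- survive(PopulationFrame(2025, cnt), c(DL = 0.02, HL = 0.10))
  expect_equal(unname(stateCounts(g)),
               unname(rbind(cnt[1, ] * 0.98, cnt[2, ] * 0.90)))
  expect_error(survive(PopulationFrame(2025, cnt), c(DL = 0.02)),
               "missing mortality")
})

test_that("a transition step is v P per group and conserves persons", {
  cnt <- rbind(a = c(10, 20, 30, 40), b = c(5, 5, 5, 5))
  colnames(cnt) <- stateLabels()
  f <- PopulationFrame(2025, cnt)
  expect_equal(stateCounts(transitionStep(f, TransitionMatrix(diag(4)))),
               stateCounts(f))
  set.seed(5)
  for (rep in 1:10) {
    M <- TransitionMatrix(randomStochastic(4))
    out <- transitionStep(f, M)
    expect_equal(rowSums(stateCounts(out)), rowSums(cnt),
                 tolerance = 1e-12)
    expect_equal(unname(stateCounts(out)["a", ]),
                 as.numeric(cnt["a", ] %*% probs(M)))
  }
  wrong <- TransitionMatrix(diag(4), horizon = 3)
  expect_error(transitionStep(f, wrong), "horizon")
})

test_that("entrants join the configured entry states", {
  f <- PopulationFrame(2025, c(900, 0, 0, 0))
  expect_equal(stateCounts(addEntrants(f, 0)), stateCounts(f))
  expect_equal(stateCounts(addEntrants(f, 50))[1, ], c(healthy = 950,
               mild = 0, moderate = 0, severe = 0))
  split <- addEntrants(f, 100, entryDist = c(0.7, 0.2, 0.1, 0))
  expect_equal(unname(stateCounts(split)[1, ]),
               c(900, 0, 0, 0) + 100 * c(0.7, 0.2, 0.1, 0))
  expect_error(addEntrants(f, -5), "non-negative")
})

test_that("scenario drift rescales worsening transitions and rebalances rows", {
  P <- annualDisabilityMatrix()
  expect_equal(probs(applyScenario(P, 0, 3)), probs(P))
  expect_equal(probs(applyScenario(TransitionMatrix(diag(4)), 0.02, 5)),
               probs(TransitionMatrix(diag(4))))
  # arithmetic oracle: above-diagonal entries x 0.98, freed mass on diagonal
  adj <- probs(applyScenario(P, 0.02, 1))
  M <- probs(P)
  for (i in 1:4) for (j in 1:4) {
    if (j > i) expect_equal(adj[i, j], M[i, j] * 0.98)
    if (j < i) expect_equal(adj[i, j], M[i, j])
  }
  expect_equal(rowSums(adj), rep(1, 4), tolerance = 1e-12,
               ignore_attr = TRUE)
  # pessimistic drift compounds upward
  pes <- probs(applyScenario(P, -0.02, 2))
  expect_equal(pes[1, 2], M[1, 2] * 1.02^2)
})

test_that("the 1000-person worked example yields 950 healthy and 90 mild", {
  we <- workedExampleDemography()
  # composite convention: mortality folded into the transition row
  pr <- projectCohort(we$frame, we$compositeMatrix, entrants = we$entrants,
                      years = 1, convention = "composite")
  y1 <- stateCounts(trajectory(pr)[[2]])
  expect_equal(y1[1, "healthy"], 950, ignore_attr = TRUE)
  expect_equal(y1[1, "mild"], 90, ignore_attr = TRUE)
  # decomposed convention (survive 1%, then transition over survivors
  # renormalized) reproduces the same bookkeeping
  M <- we$compositeMatrix / rowSums(we$compositeMatrix)
  pr2 <- projectCohort(we$frame, TransitionMatrix(M),
                       lifeTable = we$lifeTable, entrants = we$entrants,
                       years = 1, convention = "decomposed")
  expect_equal(stateCounts(trajectory(pr2)[[2]]), y1, tolerance = 1e-12)
})

test_that("projection conserves persons without mortality or entrants", {
  set.seed(21)
  cnt <- rbind(g1 = runif(4, 10, 100), g2 = runif(4, 10, 100))
  colnames(cnt) <- stateLabels()
  pr <- projectCohort(PopulationFrame(2025, cnt),
                      TransitionMatrix(randomStochastic(4)),
                      lifeTable = c(g1 = 0, g2 = 0), years = 8)
  tot <- vapply(trajectory(pr), totalPersons, numeric(1))
  expect_equal(tot, rep(sum(cnt), 9), tolerance = 1e-9)
  # per-group conservation
  g1 <- vapply(trajectory(pr), totalPersons, numeric(1), groups = "g1")
  expect_equal(g1, rep(sum(cnt["g1", ]), 9), tolerance = 1e-9)
})

test_that("optimistic drift lowers the projected severe count", {
  demo <- generateDemography(baseTotal = 5000)
  run <- function(d) projectCohort(demo$frame, annualDisabilityMatrix(),
                                   lifeTable = demo$lifeTable,
                                   entrants = demo$entrants, years = 10,
                                   drift = d)
  sev <- function(pr) stateCounts(trajectory(pr)[[11]])[, "severe"]
  expect_true(all(sev(run(0.02)) <= sev(run(0)) + 1e-12))
  expect_true(all(sev(run(-0.02)) >= sev(run(0)) - 1e-12))
})

test_that("projection is deterministic and supports aging flows", {
  demo <- generateDemography(baseTotal = 3000)
  args <- list(demo$frame, annualDisabilityMatrix(),
               lifeTable = demo$lifeTable, entrants = demo$entrants,
               years = 5)
  expect_identical(as.data.frame(do.call(projectCohort, args)),
                   as.data.frame(do.call(projectCohort, args)))
  aging <- list(map = data.frame(from = "DL.ME.TN", to = "HL.ME.TN"),
                fraction = 1 / 20)
  pr <- do.call(projectCohort, c(args, list(aging = aging)))
  pr0 <- do.call(projectCohort, args)
  y1 <- stateCounts(trajectory(pr)[[2]]); y0 <- stateCounts(trajectory(pr0)[[2]])
  expect_equal(y1["DL.ME.TN", ], y0["DL.ME.TN", ] * (1 - 1 / 20))
  expect_equal(y1["HL.ME.TN", ], y0["HL.ME.TN", ] + y0["DL.ME.TN", ] / 20)
})

test_that("growth rates follow the endpoint formula", {
  f <- PopulationFrame(2025, c(100, 0, 0, 0))
  flat <- projectCohort(f, TransitionMatrix(diag(4)), years = 3)
  expect_equal(growthRate(flat, 2025, 2028), 0)
  grow <- projectCohort(f, TransitionMatrix(diag(4)),
                        entrants = c(all = 25), years = 2)
  expect_equal(growthRate(grow, 2025, 2027), 50)  # 100 -> 150 persons
  expect_error(growthRate(flat, 2025, 2040), "years in the trajectory")
})
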