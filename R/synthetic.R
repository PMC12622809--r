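#' @include AllClasses.R
NULL

## default group-label probabilities emulating the study cohort: roughly 90%
## under 80 (DL), 48.3% male (ME), and an even urban/rural split
.GROUP_PROBS <- list(age_band = c(DL = 0.90, HL = 0.10),
                     sex = c(ME = 0.483, FE = 0.517),
                     residence = c(TN = 0.50, RL = 0.50))

.defaultTruth <- function()
  suppressWarnings(threeYearDisabilityMatrix())

#' Generate a synthetic disability-state panel
#'
#' Draws a two-wave panel: each subject's baseline state comes from
#' \code{baselineDist}, its follow-up state from the row of the true
#' transition matrix (per-subject multinomial sampling, so estimation error
#' behaves realistically), and group labels (age band DL/HL, sex ME/FE,
#' residence TN/RL) from the cohort proportions. Deterministic under a fixed
#' seed.
#'
#' @param n number of subjects (default 3000, matching the size of the
#'   emulated survey cohort).
#' @param matrices the generating truth: a
#'   \code{\linkS4class{TransitionMatrix}}, or a named list keyed by the
#'   values of \code{groupBy} for group-specific truths. Default: the pooled
#'   3-year matrix (\code{\link{threeYearDisabilityMatrix}}, renormalized).
#' @param baselineDist baseline state distribution (healthy majority is not
#'   assumed; the default reflects a mostly-disabled elderly cohort).
#' @param groupBy optional label column (\code{"age_band"}, \code{"sex"} or
#'   \code{"residence"}) keying per-group truth matrices.
#' @param year0 baseline calendar year.
#' @param seed optional RNG seed.
#' @return data.frame with columns \code{subject_id}, \code{year0},
#'   \code{state0}, \code{year1}, \code{state1}, \code{age_band},
#'   \code{sex}, \code{residence}.
#' @examples
#' pan <- generatePanel(n = 200, seed = 1)
#' table(pan$state0, pan$state1)
#' @export
generatePanel <- function(n = 3000, matrices = NULL,
                          baselineDist = c(0.15, 0.45, 0.28, 0.12),
                          groupBy = NULL, year0 = 2017, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(matrices)) matrices <- .defaultTruth()
  if (length(baselineDist) != 4 || any(baselineDist < 0) ||
      abs(sum(baselineDist) - 1) > 1e-9)
    stop("baselineDist must be a distribution over the 4 states")

  labs <- lapply(.GROUP_PROBS, function(p)
    sample(names(p), n, replace = TRUE, prob = p))

  if (is.null(groupBy)) {
    if (!is(matrices, "TransitionMatrix"))
      stop("without groupBy, 'matrices' must be a single TransitionMatrix")
    matOf <- function(i) probs(matrices)
    h <- horizon(matrices)
  } else {
    if (!groupBy %in% names(labs))
      stop("groupBy must be one of ", paste(names(labs), collapse = ", "))
    if (!is.list(matrices) ||
        !all(unique(labs[[groupBy]]) %in% names(matrices)))
      stop("'matrices' must be a named list covering all ", groupBy,
           " values")
    hs <- vapply(matrices, horizon, numeric(1))
    if (length(unique(hs)) != 1)
      stop("all group matrices must share one horizon")
    h <- hs[[1]]
    matOf <- function(i) probs(matrices[[labs[[groupBy]][i]]])
  }

  state0 <- sample.int(4, n, replace = TRUE, prob = baselineDist)
  state1 <- integer(n)
  for (i in seq_len(n))
    state1[i] <- sample.int(4, 1, prob = matOf(i)[state0[i], ])
  data.frame(subject_id = sprintf("S%05d", seq_len(n)),
             year0 = year0, state0 = state0,
             year1 = year0 + h, state1 = state1,
             age_band = labs$age_band, sex = labs$sex,
             residence = labs$residence,
             stringsAsFactors = FALSE)
}

## achievable weighted total for integer dimension scores, default item set
.dimTotal <- function(s, j, c_, r, weights, dimMax)
  totalScore(cbind(S = s, J = j, C = c_, R = r), weights = weights,
             dimensionMax = dimMax)

#' Generate item responses that score into target disability states
#'
#' Inverts the default scoring: for each subject a target total score is
#' drawn inside the band of its target state, integer dimension scores are
#' chosen to realize it (adjusting the finest-grained dimension until the
#' classification matches), and item options reproducing those dimension
#' scores are emitted. With \code{noise > 0} each subject's realized band is
#' pushed to an adjacent band with that probability, so downstream
#' classification disagrees with the target at rate \code{noise} in
#' expectation. At \code{noise = 0} the round trip
#' (responses -> \code{\link{scoreSubjects}}) reproduces the targets
#' exactly.
#'
#' Only the default item set (\code{\link{defaultScoreTable}}) is supported:
#' inversion needs the item structure, not just the score values.
#'
#' @param states integer vector of target state codes (1-4), one per
#'   subject.
#' @param noise probability of pushing a subject across a band edge.
#' @param weights,bands scoring configuration (defaults as in
#'   \code{\link{scoreSubjects}}).
#' @param seed optional RNG seed.
#' @return data.frame with columns \code{subject_id}, \code{item_id},
#'   \code{raw_option}; the realized target states are attached as
#'   attribute \code{"target_state"}.
#' @examples
#' resp <- generateItemResponses(c(1, 2, 3, 4), seed = 1)
#' scoreSubjects(resp)$state_code
#' @export
generateItemResponses <- function(states, noise = 0,
                                  weights = defaultWeights(),
                                  bands = defaultBands(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  states <- as.integer(states)
  if (any(is.na(states) | states < 1 | states > 4))
    stop("states must be integer codes 1-4")
  if (noise < 0 || noise > 1) stop("noise must be in [0, 1]")
  n <- length(states)
  if (n == 0) stop("no target states supplied")

  realized <- states
  flip <- runif(n) < noise
  if (any(flip)) {
    dir <- sample(c(-1L, 1L), sum(flip), replace = TRUE)
    r <- realized[flip] + dir
    r[r < 1] <- 2L; r[r > 4] <- 3L
    realized[flip] <- r
  }

  dimMax <- dimensionMaxima()
  ## safe target-total ranges well inside each band (state code -> range)
  ranges <- rbind(healthy = c(33, 70), mild = c(26, 29.5),
                  moderate = c(21.5, 24.5), severe = c(6, 18))
  tgt <- ranges[realized, 1] + runif(n) * (ranges[realized, 2] -
                                           ranges[realized, 1])
  f <- tgt / 100
  s <- pmin(round(f * dimMax["S"]), dimMax["S"])
  j <- pmin(round(f * dimMax["J"]), dimMax["J"])
  cc <- pmin(round(f * dimMax["C"]), dimMax["C"])
  r <- pmax(1, pmin(round(f * dimMax["R"]), dimMax["R"]))

  for (i in seq_len(n)) {   # nudge until the classification matches
    for (iter in 1:200) {
      code <- classifyDisability(
        .dimTotal(s[i], j[i], cc[i], r[i], weights, dimMax), bands)
      if (code == realized[i]) break
      if (code > realized[i]) {        # too severe: raise the total
        if (cc[i] < dimMax["C"]) cc[i] <- cc[i] + 1
        else if (s[i] < dimMax["S"]) s[i] <- s[i] + 1
        else if (r[i] < dimMax["R"]) r[i] <- r[i] + 1
        else if (j[i] < dimMax["J"]) j[i] <- j[i] + 1
        else stop("cannot raise score further; infeasible target band")
      } else {                         # too healthy: lower the total
        if (cc[i] > 0) cc[i] <- cc[i] - 1
        else if (s[i] > 0) s[i] <- s[i] - 1
        else if (r[i] > 1) r[i] <- r[i] - 1
        else if (j[i] > 0) j[i] <- j[i] - 1
        else stop("cannot lower score further; infeasible target band")
      }
    }
    if (classifyDisability(.dimTotal(s[i], j[i], cc[i], r[i], weights,
                                     dimMax), bands) != realized[i])
      stop("target band infeasible for subject ", i)
  }

  srhOpt <- c("Very bad", "Not good", "Commonly", "Good", "Very nice")
  memOpt <- c("Not good", "Commonly", "Good", "Very good", "Excellent")
  actOpt <- c("Do not participate", "Participate in an activity")
  adlOpt <- c("Unable to complete", "Nothing to")
  mmseOpt <- c("Incorrect answer", "Correct answer")

  perSubject <- function(i) {
    srh <- min(j[i], 4); disease <- j[i] - srh          # j = srh + (1 - k)
    mmse <- max(0, r[i] - 5); mem <- r[i] - mmse        # r = mmse + memory
    items <- c("self_rated_health", "disease_count",
               sprintf("adl_%d", 1:11),
               sprintf("physical_activity_%d", 1:3),
               sprintf("social_activity_%d", 1:11),
               sprintf("mmse_%d", 1:5), "memory_self")
    opts <- c(srhOpt[srh + 1], as.character(1 - disease),
              adlOpt[(seq_len(11) <= s[i]) + 1],
              actOpt[(seq_len(3) <= min(cc[i], 3)) + 1],
              actOpt[(seq_len(11) <= max(cc[i] - 3, 0)) + 1],
              mmseOpt[(seq_len(5) <= mmse) + 1],
              memOpt[mem])
    list(items = items, opts = opts)
  }
  parts <- lapply(seq_len(n), perSubject)
  nItems <- length(parts[[1]]$items)
  out <- data.frame(
    subject_id = rep(sprintf("S%05d", seq_len(n)), each = nItems),
    item_id = unlist(lapply(parts, `[[`, "items")),
    raw_option = unlist(lapply(parts, `[[`, "opts")),
    stringsAsFactors = FALSE)
  attr(out, "target_state") <- realized
  out
}

#' Generate a synthetic demographic frame
#'
#' Builds an internally consistent baseline population, life table and
#' entrant series sized for desk-scale projection runs: eight groups
#' crossing age band (DL/HL), sex (ME/FE) and residence (TN/RL) with the
#' cohort label proportions, mortality higher in the over-80 band and for
#' men, and new age-60 entrants flowing into the under-80 groups' healthy
#' state at a rate exceeding deaths (a growing elderly population).
#'
#' @param baseTotal total baseline persons (default 10000).
#' @param stateDist baseline distribution over disability states.
#' @param year0 baseline calendar year (default 2025).
#' @param entrantRate annual entrants to each DL group as a fraction of its
#'   baseline size (default 0.03).
#' @param mortality optional named per-group override of the life table.
#' @return list with elements \code{frame}
#'   (\code{\linkS4class{PopulationFrame}}), \code{lifeTable} (named
#'   vector) and \code{entrants} (named vector, constant per year).
#' @examples
#' demo <- generateDemography(baseTotal = 1000)
#' demo$lifeTable
#' @export
generateDemography <- function(baseTotal = 10000,
                               stateDist = c(0.10, 0.45, 0.30, 0.15),
                               year0 = 2025, entrantRate = 0.03,
                               mortality = NULL) {
  if (any(stateDist < 0) || abs(sum(stateDist) - 1) > 1e-9)
    stop("stateDist must be a distribution over the 4 states")
  combos <- expand.grid(age_band = c("DL", "HL"), sex = c("ME", "FE"),
                        residence = c("TN", "RL"),
                        stringsAsFactors = FALSE)
  groups <- apply(combos, 1, paste, collapse = ".")
  prop <- apply(combos, 1, function(g)
    .GROUP_PROBS$age_band[[g[1]]] * .GROUP_PROBS$sex[[g[2]]] *
      .GROUP_PROBS$residence[[g[3]]])
  counts <- outer(baseTotal * prop, stateDist)
  dimnames(counts) <- list(groups, stateLabels())
  frame <- PopulationFrame(year0, counts)

  ageBase <- c(DL = 0.02, HL = 0.08)
  sexFac <- c(ME = 1.20, FE = 0.85)
  resFac <- c(TN = 1.00, RL = 0.95)
  lifeTable <- setNames(vapply(seq_len(nrow(combos)), function(i)
    ageBase[[combos$age_band[i]]] * sexFac[[combos$sex[i]]] *
      resFac[[combos$residence[i]]], numeric(1)), groups)
  if (!is.null(mortality)) lifeTable[names(mortality)] <- mortality
  if (any(lifeTable < 0 | lifeTable > 1))
    stop("mortality rates must lie in [0, 1]")

  entrants <- setNames(rep(0, length(groups)), groups)
  isDL <- combos$age_band == "DL"
  entrants[isDL] <- entrantRate * baseTotal * prop[isDL]
  list(frame = frame, lifeTable = lifeTable, entrants = entrants)
}

#' The 1000-person worked demographic example
#'
#' One group of 1000 healthy persons, 1% annual mortality, 50 new entrants
#' per year joining the health queue -- the textbook queue-element fixture
#' whose first projected year yields 950 healthy and 90 newly mild persons
#' under the composite transition row (90% stay healthy, 9% turn mild, 1%
#' die).
#'
#' @param year0 baseline year (default 2025).
#' @return list with \code{frame}, \code{lifeTable}, \code{entrants} and
#'   \code{compositeMatrix} (the sub-stochastic 4x4 matrix whose healthy row
#'   is 0.90/0.09/0/0).
#' @export
workedExampleDemography <- function(year0 = 2025) {
  M <- matrix(c(0.90, 0.09, 0.00, 0.00,
                0.00, 0.80, 0.15, 0.00,
                0.00, 0.00, 0.90, 0.05,
                0.00, 0.00, 0.00, 0.95),
              4, 4, byrow = TRUE,
              dimnames = list(stateLabels(), stateLabels()))
  list(frame = PopulationFrame(year0, c(1000, 0, 0, 0)),
       lifeTable = c(all = 0.01),
       entrants = c(all = 50),
       compositeMatrix = M)
}

#' Agent-based microsimulation oracle for the deterministic projection
#'
#' Simulates every person individually: an annual survival draw against the
#' group's mortality rate, a transition draw from the (scenario-adjusted)
#' annual matrix row of the current state, and entrant arrivals into the
#' entry-state distribution. Counts are tallied per year. Because agents
#' are independent, the deterministic engine
#' (\code{\link{projectCohort}}, decomposed convention) is the exact
#' expectation of this simulation, which makes it an independent
#' cross-validation oracle.
#'
#' @param frame0 baseline \code{\linkS4class{PopulationFrame}} with integer
#'   counts.
#' @param matrices annual \code{\linkS4class{TransitionMatrix}} (shared) or
#'   named per-group list.
#' @param lifeTable per-group annual mortality (see \code{\link{survive}});
#'   \code{NULL} for none.
#' @param entrants \code{NULL}, named per-group vector (constant per year)
#'   or data.frame(year, group, count); fractional counts are rounded.
#' @param years number of annual steps.
#' @param drift signed annual scenario drift.
#' @param entryDist entrant state distribution.
#' @param seed optional RNG seed.
#' @return tidy data.frame (year, group, state, count) including the
#'   baseline year, comparable with
#'   \code{as.data.frame(projectCohort(...))}.
#' @export
microsimOracle <- function(frame0, matrices, lifeTable = NULL,
                           entrants = NULL, years = 10, drift = 0,
                           entryDist = c(1, 0, 0, 0), seed = NULL) {
  stopifnot(is(frame0, "PopulationFrame"))
  if (!is.null(seed)) set.seed(seed)
  cnt0 <- stateCounts(frame0)
  if (max(abs(cnt0 - round(cnt0))) > 1e-9)
    stop("microsimulation needs integer baseline counts")
  groups <- rownames(cnt0)
  nStates <- ncol(cnt0)
  mats <- .groupMatrices(matrices, groups, nStates, strict = TRUE)
  rates <- .lifeRates(lifeTable, groups)
  getEntrants <- .entrantSeries(entrants, groups)

  agents <- lapply(groups, function(g)
    rep(seq_len(nStates), times = round(cnt0[g, ])))
  names(agents) <- groups

  tally <- function(year) {
    cnt <- t(vapply(agents, function(s) tabulate(s, nStates),
                    numeric(nStates)))
    dimnames(cnt) <- dimnames(cnt0)
    data.frame(year = year,
               group = rep(groups, times = nStates),
               state = rep(colnames(cnt0), each = length(groups)),
               count = as.vector(cnt), stringsAsFactors = FALSE)
  }

  year <- frameYear(frame0)
  out <- list(tally(year))
  for (t in seq_len(years)) {
    year <- year + 1
    for (g in groups) {
      s <- agents[[g]]
      if (length(s)) {
        s <- s[runif(length(s)) >= rates[[g]]]      # survival draws
        M <- .scenarioAdjust(mats[[g]], drift, t)
        snew <- s
        for (i in seq_len(nStates)) {               # transition draws
          idx <- which(s == i)                      # origin states, pre-move
          if (length(idx))
            snew[idx] <- sample.int(nStates, length(idx), replace = TRUE,
                                    prob = M[i, ])
        }
        s <- snew
      }
      agents[[g]] <- s
    }
    ent <- getEntrants(year)
    for (g in groups) {
      k <- round(ent[[g]])
      if (k > 0)
        agents[[g]] <- c(agents[[g]],
                         sample.int(nStates, k, replace = TRUE,
                                    prob = entryDist))
    }
    out[[t + 1]] <- tally(year)
  }
  do.call(rbind, out)
}
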