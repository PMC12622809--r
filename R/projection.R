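#' @include AllClasses.R
NULL

## normalize a life table (named vector or data.frame(group, rate)) to a
## per-group named rate vector covering `groups`
.lifeRates <- function(lifeTable, groups) {
  if (is.null(lifeTable)) return(setNames(rep(0, length(groups)), groups))
  if (is.data.frame(lifeTable)) {
    if (!all(c("group", "rate") %in% names(lifeTable)))
      stop("life table data.frame needs columns 'group' and 'rate'")
    lifeTable <- setNames(lifeTable$rate, lifeTable$group)
  }
  miss <- setdiff(groups, names(lifeTable))
  if (length(miss))
    stop("life table is missing mortality rate(s) for group(s): ",
         paste(miss, collapse = ", "))
  r <- lifeTable[groups]
  if (any(r < 0 | r > 1)) stop("mortality rates must lie in [0, 1]")
  r
}

#' Apply one year of mortality to a population frame
#'
#' Multiplies every state count of each group by (1 - mortality rate).
#' Fractional persons are retained (real-valued cohort accounting). For the
#' elderly only death is considered; fertility and migration do not apply.
#'
#' @param frame a \code{\linkS4class{PopulationFrame}}.
#' @param lifeTable named numeric vector of annual mortality probabilities
#'   per group, or a data.frame with columns \code{group}, \code{rate}.
#' @return the surviving \code{PopulationFrame} (same year tag).
#' @examples
#' f <- PopulationFrame(2025, c(1000, 0, 0, 0))
#' stateCounts(survive(f, c(all = 0.01)))  # 990 healthy
#' @export
survive <- function(frame, lifeTable) {
  stopifnot(is(frame, "PopulationFrame"))
  cnt <- stateCounts(frame)
  r <- .lifeRates(lifeTable, rownames(cnt))
  PopulationFrame(frameYear(frame), cnt * (1 - r))
}

## resolve `matrices` into a per-group list of probability matrices;
## strict=TRUE enforces horizon-1 TransitionMatrix (decomposed convention),
## strict=FALSE also accepts plain (possibly sub-stochastic) matrices
.groupMatrices <- function(matrices, groups, nStates, strict = TRUE) {
  asProb <- function(m, label) {
    if (is(m, "TransitionMatrix")) {
      if (strict && horizon(m) != 1)
        stop("transition matrix", label, " has horizon ", horizon(m),
             "; an annual (horizon 1) matrix is required")
      return(probs(m))
    }
    if (!strict && is.matrix(m)) {
      if (any(m < 0) || any(rowSums(m) > 1 + .STOCH_TOL))
        stop("composite matrix", label,
             " must be non-negative with row sums <= 1")
      return(m)
    }
    stop("matrices must be TransitionMatrix objects",
         if (!strict) " or plain sub-stochastic matrices" else "")
  }
  if (is.list(matrices) && !is(matrices, "TransitionMatrix")) {
    miss <- setdiff(groups, names(matrices))
    if (length(miss))
      stop("no transition matrix for group(s): ", paste(miss, collapse = ", "))
    out <- lapply(groups, function(g)
      asProb(matrices[[g]], paste0(" for group '", g, "'")))
    names(out) <- groups
  } else {
    one <- asProb(matrices, "")
    out <- setNames(rep(list(one), length(groups)), groups)
  }
  for (g in groups)
    if (nrow(out[[g]]) != nStates)
      stop("matrix for group '", g, "' has ", nrow(out[[g]]),
           " states; frame has ", nStates)
  out
}

#' Apply one annual Markov transition to a population frame
#'
#' Each group's state-count vector v becomes v P. With a row-stochastic
#' annual matrix total persons are conserved exactly.
#'
#' @param frame a \code{\linkS4class{PopulationFrame}}.
#' @param matrices an annual (horizon 1)
#'   \code{\linkS4class{TransitionMatrix}} shared by all groups, or a named
#'   list with one per group.
#' @return the transitioned \code{PopulationFrame} (same year tag).
#' @export
transitionStep <- function(frame, matrices) {
  stopifnot(is(frame, "PopulationFrame"))
  cnt <- stateCounts(frame)
  mats <- .groupMatrices(matrices, rownames(cnt), ncol(cnt), strict = TRUE)
  out <- cnt
  for (g in rownames(cnt)) out[g, ] <- cnt[g, , drop = FALSE] %*% mats[[g]]
  PopulationFrame(frameYear(frame), out)
}

#' Add new entrants to a population frame
#'
#' Adds persons newly reaching age 60 to each group, distributed over the
#' disability states by \code{entryDist} (default: all healthy, i.e. they
#' join the health queue).
#'
#' @param frame a \code{\linkS4class{PopulationFrame}}.
#' @param entrants named numeric vector of entrant counts per group (groups
#'   not named receive 0), or a single unnamed count when the frame has one
#'   group.
#' @param entryDist distribution of entrants over states (non-negative,
#'   sums to 1).
#' @return the augmented \code{PopulationFrame}.
#' @examples
#' f <- PopulationFrame(2025, c(900, 0, 0, 0))
#' stateCounts(addEntrants(f, 50))  # 950 healthy
#' @export
addEntrants <- function(frame, entrants, entryDist = c(1, 0, 0, 0)) {
  stopifnot(is(frame, "PopulationFrame"))
  cnt <- stateCounts(frame)
  if (length(entryDist) != ncol(cnt) || any(entryDist < 0) ||
      abs(sum(entryDist) - 1) > .STOCH_TOL)
    stop("entryDist must be a distribution over the ", ncol(cnt), " states")
  if (is.null(names(entrants))) {
    if (length(entrants) == 1 && nrow(cnt) == 1)
      entrants <- setNames(entrants, rownames(cnt))
    else stop("entrants must be named by group")
  }
  if (any(entrants < 0)) stop("entrant counts must be non-negative")
  bad <- setdiff(names(entrants), rownames(cnt))
  if (length(bad)) stop("unknown group(s) in entrants: ",
                        paste(bad, collapse = ", "))
  for (g in names(entrants))
    cnt[g, ] <- cnt[g, ] + entrants[[g]] * entryDist
  PopulationFrame(frameYear(frame), cnt)
}

## scenario adjustment on a plain probability matrix: scale worsening
## (above-diagonal) entries by (1 - drift)^yearIndex, absorb the freed or
## added mass on the diagonal so row sums are unchanged
.scenarioAdjust <- function(M, drift, yearIndex) {
  if (drift == 0 || yearIndex == 0) return(M)
  f <- (1 - drift)^yearIndex
  up <- upper.tri(M)
  delta <- rowSums(M * up) * (1 - f)
  M[up] <- M[up] * f
  diag(M) <- diag(M) + delta
  if (any(diag(M) < -.STOCH_TOL) || any(M > 1 + .STOCH_TOL))
    stop("scenario infeasible: drift ", drift, " at year ", yearIndex,
         " forces a probability outside [0, 1]")
  M
}

#' Scenario-adjust an annual transition matrix
#'
#' Applies optimistic or pessimistic drift to the worsening transitions (the
#' above-diagonal entries, i.e. moves toward more severe states). Positive
#' drift (e.g. +0.02, disability transfer improving by 2% annually) scales
#' them by (1 - drift)^yearIndex; negative drift scales them up by the same
#' compounding rule. The changed mass is absorbed on the diagonal so every
#' row still sums to 1; recovery transitions are untouched.
#'
#' @param P an annual \code{\linkS4class{TransitionMatrix}}.
#' @param drift signed annual rate, |drift| < 1 (0 = baseline).
#' @param yearIndex number of years of compounding (1 = first projected
#'   year).
#' @return the adjusted \code{\linkS4class{TransitionMatrix}}.
#' @export
applyScenario <- function(P, drift, yearIndex = 1) {
  stopifnot(is(P, "TransitionMatrix"))
  if (abs(drift) >= 1) stop("|drift| must be < 1")
  if (yearIndex < 0) stop("yearIndex must be non-negative")
  TransitionMatrix(.scenarioAdjust(probs(P), drift, yearIndex),
                   horizon = horizon(P), stateNames = rownames(probs(P)))
}

## entrants argument -> function(year) named vector per group
.entrantSeries <- function(entrants, groups) {
  if (is.null(entrants))
    return(function(year) setNames(rep(0, length(groups)), groups))
  if (is.data.frame(entrants)) {
    if (!all(c("year", "group", "count") %in% names(entrants)))
      stop("entrants data.frame needs columns year, group, count")
    return(function(year) {
      rows <- entrants[entrants$year == year, , drop = FALSE]
      v <- setNames(rep(0, length(groups)), groups)
      v[rows$group] <- rows$count
      v
    })
  }
  if (is.null(names(entrants)) && length(entrants) == 1 &&
      length(groups) == 1)
    entrants <- setNames(entrants, groups)
  if (is.null(names(entrants))) stop("entrants must be named by group")
  v <- setNames(rep(0, length(groups)), groups)
  v[names(entrants)] <- entrants
  force(v)
  function(year) v
}

#' Queue-element projection of disability-state counts
#'
#' Advances a baseline population year by year. Within each projected year
#' the stages are: (1) scenario-adjust the transition matrix
#' (\code{\link{applyScenario}}), (2) survival
#' (\code{\link{survive}}; decomposed convention only), (3) Markov
#' transition (\code{\link{transitionStep}}), (4) new entrants
#' (\code{\link{addEntrants}}), (5) optional aging flow between groups.
#'
#' Two stage conventions are supported. Under \code{"decomposed"} (default)
#' mortality is applied by an explicit survival stage and the transition
#' matrices must be row-stochastic annual \code{TransitionMatrix} objects.
#' Under \code{"composite"} mortality is folded into the matrices
#' themselves: plain matrices with row sums at most 1 are accepted and each
#' row's deficit is the annual death probability (as in the textbook
#' example where a healthy person stays healthy with 90%, turns mildly
#' disabled with 9% and dies with 1%); no survival stage is applied.
#'
#' @param frame0 baseline \code{\linkS4class{PopulationFrame}}.
#' @param matrices annual transition matrix (shared) or named per-group list;
#'   see Details for the accepted forms per convention.
#' @param lifeTable per-group annual mortality (decomposed convention); see
#'   \code{\link{survive}}. Ignored under \code{"composite"}.
#' @param entrants \code{NULL} (none), a named per-group vector applied
#'   every year, or a data.frame(year, group, count).
#' @param years number of annual steps to project.
#' @param drift signed annual scenario drift (0 baseline, +0.02 optimistic,
#'   -0.02 pessimistic), compounding multiplicatively.
#' @param convention \code{"decomposed"} or \code{"composite"}.
#' @param entryDist entrant distribution over states (default all healthy).
#' @param aging optional \code{list(map = data.frame(from, to),
#'   fraction = ...)}: each year the given fraction of every \code{from}
#'   group (e.g. the under-80 band) moves to its \code{to} group (the
#'   over-80 band), applied after entrants.
#' @return a \code{\linkS4class{ProjectionResult}} whose first frame is the
#'   baseline.
#' @examples
#' f0 <- PopulationFrame(2025, c(1000, 0, 0, 0))
#' M <- matrix(c(0.90, 0.09, 0, 0,  0, 0.8, 0.15, 0,
#'               0, 0, 0.9, 0.05,   0, 0, 0, 0.95), 4, 4, byrow = TRUE)
#' pr <- projectCohort(f0, M, entrants = c(all = 50), years = 1,
#'                     convention = "composite")
#' stateCounts(trajectory(pr)[[2]])  # 950 healthy, 90 mild
#' @export
projectCohort <- function(frame0, matrices, lifeTable = NULL,
                          entrants = NULL, years = 10, drift = 0,
                          convention = c("decomposed", "composite"),
                          entryDist = c(1, 0, 0, 0), aging = NULL) {
  stopifnot(is(frame0, "PopulationFrame"))
  convention <- match.arg(convention)
  if (abs(drift) >= 1) stop("|drift| must be < 1")
  if (years < 1 || years != round(years))
    stop("years must be a positive integer number of steps")
  cnt0 <- stateCounts(frame0)
  groups <- rownames(cnt0)
  mats <- .groupMatrices(matrices, groups, ncol(cnt0),
                         strict = (convention == "decomposed"))
  rates <- if (convention == "decomposed") .lifeRates(lifeTable, groups)
           else setNames(rep(0, length(groups)), groups)
  getEntrants <- .entrantSeries(entrants, groups)
  if (!is.null(aging)) {
    if (!all(c("map", "fraction") %in% names(aging)) ||
        !all(c("from", "to") %in% names(aging$map)))
      stop("aging must be list(map = data.frame(from, to), fraction = ...)")
    if (aging$fraction < 0 || aging$fraction > 1)
      stop("aging fraction must be in [0, 1]")
  }

  frames <- vector("list", years + 1)
  frames[[1]] <- frame0
  cur <- cnt0
  year <- frameYear(frame0)
  for (t in seq_len(years)) {
    year <- year + 1
    nxt <- cur
    for (g in groups) {
      M <- .scenarioAdjust(mats[[g]], drift, t)
      v <- cur[g, , drop = FALSE] * (1 - rates[[g]])
      nxt[g, ] <- v %*% M
    }
    ent <- getEntrants(year)
    for (g in groups) nxt[g, ] <- nxt[g, ] + ent[[g]] * entryDist
    if (!is.null(aging)) {
      for (r in seq_len(nrow(aging$map))) {
        from <- aging$map$from[r]; to <- aging$map$to[r]
        if (!from %in% groups || !to %in% groups)
          stop("aging map references unknown group(s): ", from, " -> ", to)
        mv <- nxt[from, ] * aging$fraction
        nxt[from, ] <- nxt[from, ] - mv
        nxt[to, ] <- nxt[to, ] + mv
      }
    }
    cur <- nxt
    frames[[t + 1]] <- PopulationFrame(year, cur)
  }
  new("ProjectionResult", frames = frames, drift = drift,
      convention = convention)
}
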