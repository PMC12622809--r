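#' @include AllGenerics.R
NULL

.STOCH_TOL <- 1e-9

#' Ordered disability-state labels
#'
#' The four-state ordinal severity scale used throughout the package. Codes
#' 1 to 4 correspond to strictly worsening states.
#'
#' @return character vector \code{c("healthy", "mild", "moderate", "severe")}.
#' @examples
#' stateLabels()
#' @export
stateLabels <- function() c("healthy", "mild", "moderate", "severe")

## resolve user-supplied state selectors (codes or labels) to indices
.resolveStates <- function(states, labels) {
  if (is.null(states)) return(seq_along(labels))
  if (is.numeric(states)) {
    if (any(states < 1 | states > length(labels)))
      stop("state codes must be in 1..", length(labels))
    return(as.integer(states))
  }
  idx <- match(states, labels)
  if (anyNA(idx)) stop("unknown state label(s): ",
                       paste(states[is.na(idx)], collapse = ", "))
  idx
}

# ---------------------------------------------------------------------------
# TransitionMatrix
# ---------------------------------------------------------------------------

#' TransitionMatrix: a row-stochastic state transition matrix with a horizon
#'
#' Wraps a square row-stochastic probability matrix together with the time
#' horizon (in years) over which its transitions apply. Row i, column j holds
#' the probability of moving from state i to state j over \code{horizon}
#' years.
#'
#' @slot probs square numeric matrix; entries in [0, 1], each row summing to
#'   1 within 1e-9.
#' @slot horizon positive number of years.
#'
#' @seealso \code{\link{TransitionMatrix}} (constructor),
#'   \code{\link{threeYearDisabilityMatrix}},
#'   \code{\link{naiveStepTransform}}, \code{\link{calibrateAnnualMatrix}}
#' @export
setClass("TransitionMatrix",
         slots = c(probs = "matrix", horizon = "numeric"))

setValidity("TransitionMatrix", function(object) {
  P <- object@probs
  if (!is.numeric(P) || nrow(P) != ncol(P) || nrow(P) < 2)
    return("probs must be a square numeric matrix with >= 2 states")
  if (anyNA(P)) return("probs contains NA")
  if (any(P < -.STOCH_TOL) || any(P > 1 + .STOCH_TOL))
    return("entries must lie in [0, 1]")
  rs <- rowSums(P)
  if (any(abs(rs - 1) > .STOCH_TOL))
    return(sprintf("rows must sum to 1 within 1e-9 (worst deviation %.3g)",
                   max(abs(rs - 1))))
  if (length(object@horizon) != 1 || !is.finite(object@horizon) ||
      object@horizon <= 0)
    return("horizon must be a single positive number")
  TRUE
})

#' Create a TransitionMatrix
#'
#' @param probs square numeric matrix of transition probabilities.
#' @param horizon horizon in years (default 1).
#' @param stateNames optional character vector of state labels; defaults to
#'   \code{\link{stateLabels}()} for 4-state matrices.
#' @param renormalize if \code{TRUE}, rows whose sums deviate from 1 by more
#'   than 1e-9 are rescaled to sum to 1, with a warning. Printed matrices
#'   sometimes over- or under-sum through rounding; renormalization restores
#'   stochasticity without silently altering exact inputs.
#' @return a \code{\linkS4class{TransitionMatrix}}.
#' @examples
#' P <- TransitionMatrix(matrix(c(0.9, 0.1, 0.2, 0.8), 2, 2, byrow = TRUE),
#'                       horizon = 1, stateNames = c("well", "ill"))
#' probs(P)
#' @export
TransitionMatrix <- function(probs, horizon = 1, stateNames = NULL,
                             renormalize = FALSE) {
  probs <- as.matrix(probs)
  storage.mode(probs) <- "double"
  if (renormalize) {
    rs <- rowSums(probs)
    off <- abs(rs - 1) > .STOCH_TOL
    if (any(off)) {
      warning(sprintf(
        "renormalizing %d row(s) whose sums deviate from 1 (max deviation %.4g)",
        sum(off), max(abs(rs - 1))))
      probs <- probs / rs
    }
  }
  if (is.null(stateNames))
    stateNames <- if (nrow(probs) == 4) stateLabels()
                  else paste0("state", seq_len(nrow(probs)))
  dimnames(probs) <- list(from = stateNames, to = stateNames)
  new("TransitionMatrix", probs = probs, horizon = as.numeric(horizon))
}

#' @rdname probs
#' @export
setMethod("probs", "TransitionMatrix", function(object) object@probs)

#' @rdname horizon
#' @export
setMethod("horizon", "TransitionMatrix", function(object) object@horizon)

#' @rdname states
#' @export
setMethod("states", "TransitionMatrix",
          function(object) rownames(object@probs))

setMethod("show", "TransitionMatrix", function(object) {
  cat(sprintf("TransitionMatrix: %d states, horizon %g year(s)\n",
              nrow(object@probs), object@horizon))
  print(round(object@probs, 4))
  invisible(object)
})

## internal: small-integer matrix power
.matPow <- function(P, k) {
  out <- diag(nrow(P))
  for (i in seq_len(k)) out <- out %*% P
  out
}

# ---------------------------------------------------------------------------
# PopulationFrame
# ---------------------------------------------------------------------------

#' PopulationFrame: state counts by group for one calendar year
#'
#' Holds person counts by population group (rows) and disability state
#' (columns) for a single year. Counts are real-valued: the deterministic
#' projection engine uses fractional cohort accounting.
#'
#' @slot year calendar year.
#' @slot counts non-negative numeric matrix, groups x states, with dimnames.
#'
#' @seealso \code{\link{PopulationFrame}} (constructor),
#'   \code{\link{projectCohort}}
#' @export
setClass("PopulationFrame",
         slots = c(year = "numeric", counts = "matrix"))

setValidity("PopulationFrame", function(object) {
  cnt <- object@counts
  if (!is.numeric(cnt) || anyNA(cnt)) return("counts must be numeric, no NA")
  if (any(cnt < 0)) return("counts must be non-negative")
  if (is.null(rownames(cnt)) || is.null(colnames(cnt)))
    return("counts must carry group rownames and state colnames")
  if (length(object@year) != 1 || !is.finite(object@year))
    return("year must be a single finite number")
  TRUE
})

#' Create a PopulationFrame
#'
#' @param year calendar year.
#' @param counts numeric matrix (groups x states), or a numeric vector of
#'   state counts for a single group named \code{"all"}.
#' @param stateNames state labels for the columns; defaults to
#'   \code{\link{stateLabels}()}.
#' @return a \code{\linkS4class{PopulationFrame}}.
#' @examples
#' PopulationFrame(2025, c(1000, 0, 0, 0))
#' @export
PopulationFrame <- function(year, counts, stateNames = stateLabels()) {
  if (is.vector(counts))
    counts <- matrix(counts, nrow = 1, dimnames = list("all", NULL))
  counts <- as.matrix(counts)
  storage.mode(counts) <- "double"
  if (is.null(colnames(counts))) {
    if (ncol(counts) != length(stateNames))
      stop("counts has ", ncol(counts), " columns but ", length(stateNames),
           " state names were supplied")
    colnames(counts) <- stateNames
  }
  if (is.null(rownames(counts)))
    rownames(counts) <- paste0("group", seq_len(nrow(counts)))
  new("PopulationFrame", year = as.numeric(year), counts = counts)
}

#' @rdname stateCounts
#' @export
setMethod("stateCounts", "PopulationFrame", function(object) object@counts)

#' @rdname frameYear
#' @export
setMethod("frameYear", "PopulationFrame", function(object) object@year)

#' @rdname states
#' @export
setMethod("states", "PopulationFrame",
          function(object) colnames(object@counts))

#' @rdname totalPersons
#' @export
setMethod("totalPersons", "PopulationFrame",
          function(object, groups = NULL, states = NULL) {
  cnt <- object@counts
  if (!is.null(groups)) {
    bad <- setdiff(groups, rownames(cnt))
    if (length(bad)) stop("unknown group(s): ", paste(bad, collapse = ", "))
    cnt <- cnt[groups, , drop = FALSE]
  }
  j <- .resolveStates(states, colnames(cnt))
  sum(cnt[, j, drop = FALSE])
})

setMethod("show", "PopulationFrame", function(object) {
  cat(sprintf("PopulationFrame: year %g, %d group(s), %.1f persons\n",
              object@year, nrow(object@counts), sum(object@counts)))
  print(round(object@counts, 2))
  invisible(object)
})

#' @describeIn PopulationFrame-class tidy data.frame (year, group, state,
#'   count) representation.
#' @param x a \code{PopulationFrame}.
#' @param row.names,optional,... passed on for S3 compatibility (unused).
#' @export
as.data.frame.PopulationFrame <- function(x, row.names = NULL,
                                          optional = FALSE, ...) {
  cnt <- x@counts
  data.frame(year = x@year,
             group = rep(rownames(cnt), times = ncol(cnt)),
             state = rep(colnames(cnt), each = nrow(cnt)),
             count = as.vector(cnt),
             stringsAsFactors = FALSE)
}

# ---------------------------------------------------------------------------
# CalibrationResult
# ---------------------------------------------------------------------------

#' CalibrationResult: outcome of annual-matrix calibration
#'
#' Returned by \code{\link{calibrateAnnualMatrix}}. Holds the calibrated
#' horizon-1 matrix, the per-state relative errors of the horizon-year count
#' projection, the optimizer's iteration count, and a convergence flag
#' (maximum error at or below the tolerance).
#'
#' @slot annual the calibrated \code{\linkS4class{TransitionMatrix}}
#'   (horizon 1).
#' @slot perStateError numeric vector of per-state relative errors.
#' @slot naiveError per-state relative errors of the uncalibrated step
#'   transform, for reference.
#' @slot iterations number of objective evaluations used by the optimizer.
#' @slot converged logical.
#' @slot tolerance the tolerance calibration was run with.
#' @export
setClass("CalibrationResult",
         slots = c(annual = "TransitionMatrix",
                   perStateError = "numeric",
                   naiveError = "numeric",
                   iterations = "numeric",
                   converged = "logical",
                   tolerance = "numeric"))

setValidity("CalibrationResult", function(object) {
  if (object@converged &&
      max(object@perStateError) > object@tolerance + .STOCH_TOL)
    return("converged = TRUE but max per-state error exceeds tolerance")
  TRUE
})

#' @rdname annualMatrix
#' @export
setMethod("annualMatrix", "CalibrationResult", function(object) object@annual)

#' @rdname perStateError
#' @export
setMethod("perStateError", "CalibrationResult",
          function(object) object@perStateError)

#' @rdname converged
#' @export
setMethod("converged", "CalibrationResult", function(object) object@converged)

setMethod("show", "CalibrationResult", function(object) {
  cat(sprintf(
    "CalibrationResult: %s (max error %.4g%%, tolerance %g%%, %g evaluations)\n",
    if (object@converged) "converged" else "NOT converged",
    100 * max(object@perStateError), 100 * object@tolerance,
    object@iterations))
  cat("calibrated annual matrix:\n")
  print(round(object@annual@probs, 4))
  invisible(object)
})

# ---------------------------------------------------------------------------
# ProjectionResult
# ---------------------------------------------------------------------------

#' ProjectionResult: a projected population trajectory
#'
#' Returned by \code{\link{projectCohort}}. Holds one
#' \code{\linkS4class{PopulationFrame}} per year (baseline first) plus the
#' scenario drift and stage convention used.
#'
#' @slot frames list of \code{PopulationFrame}, years strictly increasing.
#' @slot drift signed annual scenario drift (0 = baseline).
#' @slot convention \code{"decomposed"} or \code{"composite"} (see
#'   \code{\link{projectCohort}}).
#' @export
setClass("ProjectionResult",
         slots = c(frames = "list", drift = "numeric",
                   convention = "character"))

setValidity("ProjectionResult", function(object) {
  yrs <- vapply(object@frames, frameYear, numeric(1))
  if (length(yrs) && any(diff(yrs) <= 0))
    return("trajectory years must be strictly increasing")
  TRUE
})

#' @rdname trajectory
#' @export
setMethod("trajectory", "ProjectionResult", function(object) object@frames)

setMethod("show", "ProjectionResult", function(object) {
  yrs <- vapply(object@frames, frameYear, numeric(1))
  tot <- vapply(object@frames, totalPersons, numeric(1))
  cat(sprintf(
    "ProjectionResult: %d year(s) %g-%g, drift %+g, %s convention\n",
    length(yrs), min(yrs), max(yrs), object@drift, object@convention))
  print(data.frame(year = yrs, persons = round(tot, 1)), row.names = FALSE)
  invisible(object)
})

#' @describeIn ProjectionResult-class tidy data.frame (year, group, state,
#'   count) over the whole trajectory.
#' @param x a \code{ProjectionResult}.
#' @param row.names,optional,... passed on for S3 compatibility (unused).
#' @export
as.data.frame.ProjectionResult <- function(x, row.names = NULL,
                                           optional = FALSE, ...) {
  do.call(rbind, lapply(x@frames, as.data.frame))
}

#' @rdname growthRate
#' @export
setMethod("growthRate", "ProjectionResult",
          function(object, from, to, groups = NULL, states = NULL) {
  yrs <- vapply(object@frames, frameYear, numeric(1))
  i <- match(from, yrs); j <- match(to, yrs)
  if (is.na(i) || is.na(j))
    stop("both 'from' and 'to' must be years in the trajectory (",
         min(yrs), "-", max(yrs), ")")
  n0 <- totalPersons(object@frames[[i]], groups = groups, states = states)
  n1 <- totalPersons(object@frames[[j]], groups = groups, states = states)
  if (n0 == 0) stop("growth rate undefined: aggregate is 0 in year ", from)
  100 * (n1 - n0) / n0
})
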