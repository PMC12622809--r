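#' @include AllGenerics.R
NULL

#' Transition probabilities of a \code{TransitionMatrix}
#'
#' @param object a \code{\linkS4class{TransitionMatrix}}.
#' @return the row-stochastic numeric matrix of transition probabilities.
#' @export
setGeneric("probs", function(object) standardGeneric("probs"))

#' Horizon (in years) of a \code{TransitionMatrix}
#'
#' @param object a \code{\linkS4class{TransitionMatrix}}.
#' @return the horizon in years (positive number).
#' @export
setGeneric("horizon", function(object) standardGeneric("horizon"))

#' State labels of a disability-state object
#'
#' @param object a \code{\linkS4class{TransitionMatrix}} or
#'   \code{\linkS4class{PopulationFrame}}.
#' @return character vector of state labels, ordered from healthiest to most
#'   severe.
#' @export
setGeneric("states", function(object) standardGeneric("states"))

#' State counts of a \code{PopulationFrame}
#'
#' @param object a \code{\linkS4class{PopulationFrame}}.
#' @return numeric matrix of person counts, groups in rows and disability
#'   states in columns.
#' @export
setGeneric("stateCounts", function(object) standardGeneric("stateCounts"))

#' Calendar year of a \code{PopulationFrame}
#'
#' @param object a \code{\linkS4class{PopulationFrame}}.
#' @return the calendar year.
#' @export
setGeneric("frameYear", function(object) standardGeneric("frameYear"))

#' Total persons in a population object
#'
#' @param object a \code{\linkS4class{PopulationFrame}}.
#' @param groups optional character vector restricting to some groups.
#' @param states optional vector (integer codes or labels) restricting to some
#'   disability states.
#' @return total person count (possibly fractional: the deterministic engine
#'   uses real-valued cohort accounting).
#' @export
setGeneric("totalPersons",
           function(object, groups = NULL, states = NULL)
             standardGeneric("totalPersons"))

#' Calibrated annual matrix of a \code{CalibrationResult}
#'
#' @param object a \code{\linkS4class{CalibrationResult}}.
#' @return the calibrated horizon-1 \code{\linkS4class{TransitionMatrix}}.
#' @export
setGeneric("annualMatrix", function(object) standardGeneric("annualMatrix"))

#' Per-state relative calibration errors
#'
#' @param object a \code{\linkS4class{CalibrationResult}}.
#' @return numeric vector of per-state relative errors
#'   |actual - predicted| / actual between counts projected by the multi-year
#'   matrix and counts projected by the calibrated annual matrix applied
#'   horizon times.
#' @export
setGeneric("perStateError", function(object) standardGeneric("perStateError"))

#' Did calibration reach its tolerance?
#'
#' @param object a \code{\linkS4class{CalibrationResult}}.
#' @return logical: \code{TRUE} when the maximum per-state relative error is
#'   at or below the calibration tolerance.
#' @export
setGeneric("converged", function(object) standardGeneric("converged"))

#' Projection trajectory
#'
#' @param object a \code{\linkS4class{ProjectionResult}}.
#' @return list of \code{\linkS4class{PopulationFrame}} objects, one per year,
#'   in increasing year order.
#' @export
setGeneric("trajectory", function(object) standardGeneric("trajectory"))

#' Growth rate of a projected aggregate between two years
#'
#' Computes 100 * (N_to - N_from) / N_from for a chosen aggregate of the
#' projected population.
#'
#' @param object a \code{\linkS4class{ProjectionResult}}.
#' @param from,to calendar years present in the trajectory.
#' @param groups optional character vector restricting the aggregate to some
#'   groups.
#' @param states optional vector (codes or labels) restricting the aggregate
#'   to some disability states.
#' @return growth rate in percent.
#' @export
setGeneric("growthRate",
           function(object, from, to, groups = NULL, states = NULL)
             standardGeneric("growthRate"))
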