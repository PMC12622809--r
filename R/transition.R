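#' @include AllClasses.R
NULL

#' Pooled 3-year disability transition matrix (2017-2020 panel estimate)
#'
#' The pooled three-year transition probability matrix between the four
#' disability states, as estimated from the 2017 and 2020 waves of a Chinese
#' elderly panel survey and shipped here as the package's default multi-year
#' matrix and regression anchor. As printed, rows 1 and 2 sum to 1.0036 (a
#' rounding artifact); with \code{renormalize = TRUE} (the default) each row
#' is rescaled to sum to 1, with a warning.
#'
#' The severe row has a structural zero for severe-to-healthy recovery.
#'
#' @param renormalize rescale rows to sum to exactly 1 (default TRUE). With
#'   \code{renormalize = FALSE} the bit-exact printed values are returned as
#'   a plain matrix (they are not row-stochastic, so they cannot populate a
#'   \code{TransitionMatrix}).
#' @return a \code{\linkS4class{TransitionMatrix}} with horizon 3, or the
#'   raw printed matrix when \code{renormalize = FALSE}.
#' @examples
#' suppressWarnings(threeYearDisabilityMatrix())
#' @export
threeYearDisabilityMatrix <- function(renormalize = TRUE) {
  P <- matrix(c(0.3382, 0.5819, 0.0798, 0.0037,
                0.0602, 0.6669, 0.2515, 0.0250,
                0.0198, 0.3869, 0.4876, 0.1057,
                0.0000, 0.1100, 0.2400, 0.6500),
              nrow = 4, byrow = TRUE,
              dimnames = list(stateLabels(), stateLabels()))
  if (!renormalize) return(P)
  TransitionMatrix(P, horizon = 3, renormalize = TRUE)
}

#' Published calibrated annual disability transition matrix
#'
#' The one-year transition matrix published alongside the three-year matrix
#' of \code{\link{threeYearDisabilityMatrix}}, obtained there by step-size
#' transformation plus correction. Shipped as a reference object and as a
#' default generating truth for synthetic panels. Note that this package's
#' own calibrator (\code{\link{calibrateAnnualMatrix}}) does not reproduce
#' this matrix entry-for-entry: the published correction procedure is not
#' fully specified, and the cube of this matrix diverges substantially from
#' the three-year matrix.
#'
#' @return a \code{\linkS4class{TransitionMatrix}} with horizon 1.
#' @export
annualDisabilityMatrix <- function() {
  P <- matrix(c(0.4830, 0.4129, 0.0944, 0.0097,
                0.0347, 0.7359, 0.1989, 0.0305,
                0.0185, 0.2760, 0.6233, 0.0822,
                0.0028, 0.1079, 0.1869, 0.7024),
              nrow = 4, byrow = TRUE)
  TransitionMatrix(P, horizon = 1)
}

#' Estimate a transition matrix from panel observations
#'
#' Maximum-likelihood (row-proportion) estimate of the discrete-time Markov
#' transition matrix: \code{P[i, j]} is the fraction of subjects observed in
#' state i at baseline that are in state j at follow-up.
#'
#' @param panel data.frame with integer state columns \code{state0} and
#'   \code{state1} (codes 1-4), one row per subject.
#' @param horizon years between baseline and follow-up (attached to the
#'   result).
#' @param by optional character vector of grouping columns in \code{panel}
#'   (e.g. \code{c("age_band", "sex")}); a named list of matrices, one per
#'   group combination, is then returned.
#' @param priorRows optional matrix of fallback rows (4 x 4): when an origin
#'   state has no observations its row is taken from \code{priorRows}
#'   instead of failing.
#' @param nStates number of states (default 4).
#' @return a \code{\linkS4class{TransitionMatrix}}, or a named list of them
#'   when \code{by} is given.
#' @examples
#' pan <- data.frame(state0 = c(1, 1, 2, 2), state1 = c(1, 2, 2, 2))
#' probs(estimateTransitionMatrix(pan, horizon = 3))
#' @export
estimateTransitionMatrix <- function(panel, horizon = 3, by = NULL,
                                     priorRows = NULL, nStates = 4) {
  if (!all(c("state0", "state1") %in% names(panel)))
    stop("panel must have columns state0 and state1")
  if (nrow(panel) == 0) stop("panel is empty")
  if (!is.null(by)) {
    bad <- setdiff(by, names(panel))
    if (length(bad)) stop("grouping column(s) not in panel: ",
                          paste(bad, collapse = ", "))
    keys <- interaction(panel[by], sep = ".", drop = TRUE)
    return(lapply(split(panel, keys), estimateTransitionMatrix,
                  horizon = horizon, priorRows = priorRows,
                  nStates = nStates))
  }
  s0 <- as.integer(panel$state0); s1 <- as.integer(panel$state1)
  if (any(is.na(s0) | is.na(s1) | s0 < 1 | s0 > nStates |
          s1 < 1 | s1 > nStates))
    stop("states must be integer codes in 1..", nStates)
  cnt <- table(factor(s0, levels = seq_len(nStates)),
               factor(s1, levels = seq_len(nStates)))
  cnt <- matrix(as.numeric(cnt), nStates, nStates)
  rowN <- rowSums(cnt)
  P <- cnt
  for (i in seq_len(nStates)) {
    if (rowN[i] > 0) {
      P[i, ] <- cnt[i, ] / rowN[i]
    } else if (!is.null(priorRows)) {
      P[i, ] <- priorRows[i, ] / sum(priorRows[i, ])
    } else {
      stop("origin state ", i, " has no observations; supply priorRows")
    }
  }
  TransitionMatrix(P, horizon = horizon,
                   stateNames = if (nStates == 4) stateLabels() else NULL)
}

#' Step-size transform of a multi-year transition matrix
#'
#' Converts a horizon-h row-stochastic matrix to an approximate annual one by
#' dividing every off-diagonal entry by h and resetting each diagonal to one
#' minus its row's off-diagonal sum. The result is row-stochastic by
#' construction (for a stochastic input the off-diagonal row sums are at most
#' 1, so divided by h >= 1 the diagonal stays non-negative). This is a
#' first-order approximation to the h-th matrix root; it is normally
#' followed by \code{\link{calibrateAnnualMatrix}}.
#'
#' @param P a \code{\linkS4class{TransitionMatrix}} with horizon >= 1.
#' @return a \code{\linkS4class{TransitionMatrix}} with horizon 1.
#' @examples
#' P2 <- TransitionMatrix(matrix(c(0.7, 0.3, 0.3, 0.7), 2, 2), horizon = 3)
#' probs(naiveStepTransform(P2))  # off-diagonals 0.1, diagonals 0.9
#' @export
naiveStepTransform <- function(P) {
  stopifnot(is(P, "TransitionMatrix"))
  h <- horizon(P)
  G <- probs(P) / h
  diag(G) <- 0
  d <- 1 - rowSums(G)
  if (any(d < -.STOCH_TOL))
    stop("off-diagonal mass divided by the horizon exceeds 1; ",
         "cannot form a probability row")
  diag(G) <- pmax(d, 0)
  TransitionMatrix(G, horizon = 1, stateNames = rownames(probs(P)))
}

#' Relative correction error
#'
#' \code{e = |actual - estimated| / actual}, the correction-error measure
#' used to judge whether an annualized matrix reproduces multi-year state
#' counts.
#'
#' @param actual actual value(s); must be non-zero.
#' @param estimated predicted value(s).
#' @return relative error(s), same length as the inputs.
#' @examples
#' relativeError(100, 95)   # 0.05
#' relativeError(200, 210)  # 0.05
#' @export
relativeError <- function(actual, estimated) {
  if (any(actual == 0))
    stop("relative error undefined: actual value is 0 (degenerate state)")
  abs(actual - estimated) / abs(actual)
}

#' Calibrate an annual transition matrix against multi-year counts
#'
#' Searches for a row-stochastic annual matrix P1 whose h-fold application to
#' an initial state-count vector reproduces the counts given by one
#' application of the horizon-h matrix P. The objective is the maximum
#' per-state relative error (\code{\link{relativeError}}); the search starts
#' from \code{\link{naiveStepTransform}(P)}, parameterizes the free entries
#' of each row through a softmax (so every candidate is row-stochastic), and
#' minimizes the sum of squared per-state relative errors by quasi-Newton
#' descent. Structural zeros of P (off-diagonal entries equal to 0, such as
#' severe-to-healthy recovery) are held at 0. The procedure is deterministic.
#'
#' If optimization fails to improve on the step transform, the step
#' transform itself is returned. Failure to reach the tolerance is reported
#' via \code{converged(result) == FALSE}, not as an error.
#'
#' @param P a \code{\linkS4class{TransitionMatrix}} with horizon h >= 2.
#' @param initialCounts positive state-count vector (one entry per state).
#' @param tolerance maximum acceptable per-state relative error
#'   (default 0.05).
#' @param maxit optimizer iteration cap.
#' @return a \code{\linkS4class{CalibrationResult}}.
#' @examples
#' P3 <- suppressWarnings(threeYearDisabilityMatrix())
#' cal <- calibrateAnnualMatrix(P3, rep(1000, 4))
#' converged(cal)
#' max(perStateError(cal)) <= 0.05
#' @export
calibrateAnnualMatrix <- function(P, initialCounts, tolerance = 0.05,
                                  maxit = 1000) {
  stopifnot(is(P, "TransitionMatrix"))
  h <- horizon(P)
  if (h < 2 || h != round(h))
    stop("P must have an integer horizon of at least 2 years")
  k <- nrow(probs(P))
  if (length(initialCounts) != k || any(initialCounts <= 0))
    stop("initialCounts must be ", k, " positive values")
  if (tolerance <= 0 || tolerance >= 1) stop("tolerance must be in (0, 1)")

  Pm <- probs(P)
  target <- as.numeric(initialCounts %*% Pm)
  naiveP <- probs(naiveStepTransform(P))

  ## structural zeros: off-diagonal entries that are exactly 0 in P stay 0
  free <- Pm > 0
  diag(free) <- TRUE

  predict1 <- function(P1)
    as.numeric(initialCounts %*% .matPow(P1, h))
  errs <- function(P1) relativeError(target, predict1(P1))

  build <- function(theta) {
    M <- matrix(0, k, k)
    M[free] <- exp(theta)
    M / rowSums(M)
  }
  theta0 <- log(pmax(naiveP[free], 1e-8))
  obj <- function(theta) sum(errs(build(theta))^2)
  fit <- optim(theta0, obj, method = "BFGS",
               control = list(maxit = maxit, reltol = 1e-14))
  P1 <- build(fit$par)
  e <- errs(P1)
  eNaive <- errs(naiveP)
  if (max(e) > max(eNaive)) {  # never worse than the starting transform
    P1 <- naiveP
    e <- eNaive
  }
  ann <- TransitionMatrix(P1, horizon = 1, stateNames = rownames(Pm))
  new("CalibrationResult",
      annual = ann,
      perStateError = e,
      naiveError = eNaive,
      iterations = as.numeric(fit$counts[["function"]]),
      converged = max(e) <= tolerance,
      tolerance = tolerance)
}
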