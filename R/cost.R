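#' @include AllClasses.R
NULL

#' Default long-term care cost parameters
#'
#' Per-capita monthly care cost parameters by care mode and disability
#' level, from the 2020 wave of the underlying elderly survey: d = nursing
#' days per month, T = nursing hours per day, zeta = disability-level cost
#' coefficient, psi = time value of nursing staff in USD per hour (shared
#' across modes). Institutional care has level-specific rows; home care has
#' a single row applied to all levels (\code{level = "all"}). Community care
#' is supported structurally but ships without default parameters.
#'
#' @return data.frame with columns \code{mode}, \code{level}, \code{d},
#'   \code{T}, \code{zeta}, \code{psi}.
#' @examples
#' p <- defaultCostParams()
#' round(monthlyCareCost(p$d, p$T, p$zeta, p$psi), 2)
#' @export
defaultCostParams <- function() {
  data.frame(
    mode  = c("institutional", "institutional", "institutional", "home"),
    level = c("mild", "moderate", "severe", "all"),
    d     = c(20.94, 21.95, 24.42, 21.63),
    T     = c(4.46, 4.84, 8.58, 4.83),
    zeta  = c(1.81, 1.93, 2.16, 1.24),
    psi   = c(3.07, 3.07, 3.07, 3.07),
    stringsAsFactors = FALSE)
}

#' Per-capita monthly long-term care cost
#'
#' Computes C = d * T * zeta * psi: nursing days per month times daily
#' nursing hours times the disability-level cost coefficient times the
#' hourly time value of nursing staff. Multiplicatively homogeneous in each
#' factor.
#'
#' @param d nursing days per month, in (0, 31].
#' @param T nursing hours per day, in (0, 24].
#' @param zeta disability-level cost coefficient, positive.
#' @param psi time value of nursing staff, currency per hour, positive.
#' @return cost in currency units per person-month (vectorized).
#' @examples
#' monthlyCareCost(20.94, 4.46, 1.81, 3.07)  # 518.95 USD/month
#' @export
monthlyCareCost <- function(d, T, zeta, psi) {
  if (any(d <= 0) || any(d > 31)) stop("d must lie in (0, 31] days/month")
  if (any(T <= 0) || any(T > 24)) stop("T must lie in (0, 24] hours/day")
  if (any(zeta <= 0)) stop("zeta must be positive")
  if (any(psi <= 0)) stop("psi must be positive")
  d * T * zeta * psi
}

## look up the (level, mode) parameter row, falling back to level == "all"
.costFor <- function(level, mode, params) {
  hit <- params[params$mode == mode & params$level == level, , drop = FALSE]
  if (nrow(hit) == 0)
    hit <- params[params$mode == mode & params$level == "all", , drop = FALSE]
  if (nrow(hit) == 0)
    stop("no cost parameters for mode '", mode, "', level '", level, "'")
  monthlyCareCost(hit$d[1], hit$T[1], hit$zeta[1], hit$psi[1])
}

#' Default care-mode shares
#'
#' Share of each disabled severity level cared for under each mode. The
#' shipped default assigns every level fully to home care, the dominant
#' mode in the study population; override to split levels across
#' institutional/home/community care.
#'
#' @return data.frame with columns \code{level}, \code{mode}, \code{share}.
#' @export
defaultModeShares <- function() {
  data.frame(level = c("mild", "moderate", "severe"),
             mode = "home", share = 1, stringsAsFactors = FALSE)
}

#' Aggregate long-term care costs over a projected trajectory
#'
#' For every projected year, severity level and care mode, computes the
#' annual total cost: headcount in that level times the mode share times the
#' per-capita monthly cost times 12. Healthy persons incur no care cost.
#' Additive over disjoint population partitions.
#'
#' @param projection a \code{\linkS4class{ProjectionResult}} or a tidy
#'   trajectory data.frame with columns \code{year}, \code{state},
#'   \code{count}.
#' @param params cost parameter table, see \code{\link{defaultCostParams}}.
#' @param modeShares data.frame(level, mode, share); shares per level must
#'   sum to 1. Default: \code{\link{defaultModeShares}}.
#' @return data.frame with columns \code{year}, \code{level}, \code{mode},
#'   \code{per_capita_monthly}, \code{headcount}, \code{annual_total}.
#' @export
aggregateCosts <- function(projection, params = defaultCostParams(),
                           modeShares = defaultModeShares()) {
  traj <- if (is(projection, "ProjectionResult")) as.data.frame(projection)
          else projection
  if (!all(c("year", "state", "count") %in% names(traj)))
    stop("projection must provide year, state and count columns")
  shareSums <- tapply(modeShares$share, modeShares$level, sum)
  if (any(abs(shareSums - 1) > 1e-9))
    stop("mode shares must sum to 1 within each level")
  disabled <- setdiff(stateLabels(), "healthy")
  heads <- aggregate(count ~ year + state, data = traj, FUN = sum)
  heads <- heads[heads$state %in% disabled, , drop = FALSE]
  rows <- merge(heads, modeShares, by.x = "state", by.y = "level")
  if (nrow(rows) == 0) stop("no disabled headcounts matched the mode shares")
  rows$per_capita_monthly <- mapply(.costFor, rows$state, rows$mode,
                                    MoreArgs = list(params = params))
  rows$headcount <- rows$count * rows$share
  rows$annual_total <- rows$per_capita_monthly * rows$headcount * 12
  out <- rows[order(rows$year, rows$state, rows$mode),
              c("year", "state", "mode", "per_capita_monthly", "headcount",
                "annual_total")]
  names(out)[2] <- "level"
  rownames(out) <- NULL
  out
}

#' Fixed-proportion service demand projection
#'
#' Scales the projected total elderly population by fixed need proportions
#' (assumed constant over the projection horizon) to obtain per-service
#' annual demand counts.
#'
#' @param projection a \code{\linkS4class{ProjectionResult}} or tidy
#'   trajectory data.frame (year, state, count).
#' @param specs data.frame with columns \code{service} and
#'   \code{proportion} (each in [0, 1]).
#' @return data.frame with columns \code{year}, \code{service},
#'   \code{population}, \code{demand}.
#' @examples
#' f0 <- PopulationFrame(2025, c(600, 250, 100, 50))
#' pr <- projectCohort(f0, TransitionMatrix(diag(4)), years = 1)
#' serviceDemand(pr, data.frame(service = "daily care", proportion = 0.132))
#' @export
serviceDemand <- function(projection, specs) {
  traj <- if (is(projection, "ProjectionResult")) as.data.frame(projection)
          else projection
  if (!all(c("service", "proportion") %in% names(specs)))
    stop("specs must have columns 'service' and 'proportion'")
  if (any(specs$proportion < 0 | specs$proportion > 1))
    stop("proportions must lie in [0, 1]")
  pop <- aggregate(count ~ year, data = traj, FUN = sum)
  out <- merge(pop, specs)
  out$demand <- out$count * out$proportion
  out <- out[order(out$service, out$year),
             c("year", "service", "count", "demand")]
  names(out)[3] <- "population"
  rownames(out) <- NULL
  out
}
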