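#' @include AllClasses.R
NULL

## Options recorded as vague during data collection; they carry no score and
## flag the record for complete-case removal (or modal imputation).
.VAGUE_OPTIONS <- c("Not evaluated", "Unclear")

#' Default item score table
#'
#' The item-level score assignment used by the four-dimension disability
#' assessment: self-rated health and disease burden (dimension J), physical
#' and social activity participation (C), activities of daily living /
#' self-care (S), and a short mental-state examination plus self-rated memory
#' (R). The disease item is scored 1 for no illness, 0 for one disease
#' category, and one further point deducted per additional category
#' (negative item scores act as deductions; dimension totals are floored at
#' 0). Every item also accepts the vague options \code{"Not evaluated"} and
#' \code{"Unclear"}, which score \code{NA} and flag the record as removable.
#'
#' @return data.frame with columns \code{item_id}, \code{dimension} (one of
#'   \code{"S"}, \code{"J"}, \code{"C"}, \code{"R"}), \code{option},
#'   \code{score}.
#' @examples
#' head(defaultScoreTable())
#' @export
defaultScoreTable <- function() {
  row <- function(item, dim, option, score)
    data.frame(item_id = item, dimension = dim, option = option,
               score = score, stringsAsFactors = FALSE)
  tab <- list(
    row("self_rated_health", "J",
        c("Very bad", "Not good", "Commonly", "Good", "Very nice"), 0:4),
    ## number of disease categories present (chronic disease, hypertension,
    ## diabetes, arthritis/rheumatoid, digestive); 1 - count, deductions kept
    row("disease_count", "J", as.character(0:5), 1 - (0:5))
  )
  for (i in 1:3)
    tab <- c(tab, list(row(sprintf("physical_activity_%d", i), "C",
                           c("Participate in an activity",
                             "Do not participate"), c(1L, 0L))))
  for (i in 1:11)
    tab <- c(tab, list(row(sprintf("social_activity_%d", i), "C",
                           c("Participate in an activity",
                             "Do not participate"), c(1L, 0L))))
  for (i in 1:11)
    tab <- c(tab, list(row(sprintf("adl_%d", i), "S",
                           c("Unable to complete",
                             "Having difficulties and needing help",
                             "Difficult to complete",
                             "Nothing to"), c(0L, 0L, 0L, 1L))))
  for (i in 1:5)
    tab <- c(tab, list(row(sprintf("mmse_%d", i), "R",
                           c("Correct answer", "Incorrect answer"),
                           c(1L, 0L))))
  tab <- c(tab, list(row("memory_self", "R",
                         c("Not good", "Commonly", "Good", "Very good",
                           "Excellent"), 1:5)))
  tab <- do.call(rbind, tab)
  vague <- unique(tab[, c("item_id", "dimension")])
  vague <- merge(vague, data.frame(option = .VAGUE_OPTIONS, score = NA_real_))
  rbind(tab, vague[, c("item_id", "dimension", "option", "score")])
}

#' Default dimension weights
#'
#' Weights for the four assessment dimensions: physical function (S), health
#' and disease (J), activity participation (C) and cognition (R). They sum to
#' 1 exactly.
#'
#' @return named numeric vector \code{c(S, J, C, R)}.
#' @export
defaultWeights <- function()
  c(S = 0.2513, J = 0.3201, C = 0.1968, R = 0.2318)

#' Default severity band edges
#'
#' Upper edges of the severe, moderate and mild score bands (5-point group
#' distance): totals at or below 20 are severe, (20, 25] moderate,
#' (25, 30] mild, and anything above 30 healthy. Fractional totals use the
#' band edges as half-open intervals.
#'
#' @return named numeric vector \code{c(severe = 20, moderate = 25,
#'   mild = 30)}.
#' @export
defaultBands <- function() c(severe = 20, moderate = 25, mild = 30)

#' Maximum attainable score per dimension
#'
#' Sums, per dimension, the largest positive score of each item in a score
#' table. Used to rescale dimension totals to percent-of-maximum before
#' weighting (see \code{\link{totalScore}}).
#'
#' @param scoreTable a score table as returned by
#'   \code{\link{defaultScoreTable}}.
#' @return named numeric vector with elements S, J, C, R.
#' @examples
#' dimensionMaxima()  # S = 11, J = 5, C = 14, R = 10
#' @export
dimensionMaxima <- function(scoreTable = defaultScoreTable()) {
  ok <- !is.na(scoreTable$score)
  itemMax <- tapply(pmax(scoreTable$score[ok], 0),
                    list(scoreTable$item_id[ok], scoreTable$dimension[ok]),
                    max)
  out <- vapply(c("S", "J", "C", "R"),
                function(d) sum(itemMax[, d], na.rm = TRUE), numeric(1))
  out
}

.checkWeights <- function(weights) {
  if (length(weights) != 4 || anyNA(weights))
    stop("weights must be 4 finite values (S, J, C, R)")
  if (any(weights <= 0) || any(weights >= 1))
    stop("each weight must lie strictly in (0, 1)")
  if (abs(sum(weights) - 1) > 1e-9)
    stop("weights must sum to 1 within 1e-9 (got ", sum(weights), ")")
  if (is.null(names(weights))) names(weights) <- c("S", "J", "C", "R")
  weights[c("S", "J", "C", "R")]
}

#' Score one item response
#'
#' Looks up the point value assigned to a raw option of a questionnaire item.
#' Vague options (\code{"Not evaluated"}, \code{"Unclear"}) return \code{NA}
#' and signal a warning of class \code{"removableRecord"} so callers can drop
#' or impute the record.
#'
#' @param itemId item identifier present in the score table.
#' @param rawOption the recorded answer.
#' @param scoreTable score table, see \code{\link{defaultScoreTable}}.
#' @return integer-valued score (possibly negative for deduction items), or
#'   \code{NA} for vague options.
#' @examples
#' scoreItem("self_rated_health", "Very nice")  # 4
#' scoreItem("mmse_1", "Correct answer")        # 1
#' @export
scoreItem <- function(itemId, rawOption, scoreTable = defaultScoreTable()) {
  rows <- scoreTable[scoreTable$item_id == itemId, , drop = FALSE]
  if (nrow(rows) == 0)
    stop("unknown item '", itemId, "': not in the score table")
  hit <- match(rawOption, rows$option)
  if (is.na(hit))
    stop("illegal option '", rawOption, "' for item '", itemId, "'")
  sc <- rows$score[hit]
  if (is.na(sc)) {
    warning(warningCondition(
      paste0("item '", itemId, "': vague option '", rawOption,
             "' -- record flagged for removal"),
      class = "removableRecord"))
    return(NA_real_)
  }
  sc
}

#' Aggregate scored responses into dimension totals
#'
#' Sums assigned scores per dimension (S, J, C, R). Dimensions with no
#' responses contribute 0. Because deduction items can drive a sum negative,
#' each dimension total is floored at 0.
#'
#' @param responses data.frame with columns \code{dimension} and
#'   \code{assigned_score}, all scores non-missing.
#' @return named numeric vector \code{c(S, J, C, R)} of non-negative totals.
#' @examples
#' aggregateDimensions(data.frame(dimension = c("S", "J"),
#'                                assigned_score = c(1, 3)))
#' @export
aggregateDimensions <- function(responses) {
  if (NROW(responses) == 0) stop("no scored responses to aggregate")
  if (anyNA(responses$assigned_score))
    stop("responses contain unscored (NA) records; remove or impute first")
  bad <- setdiff(unique(responses$dimension), c("S", "J", "C", "R"))
  if (length(bad))
    stop("unknown dimension code(s): ", paste(bad, collapse = ", "))
  out <- c(S = 0, J = 0, C = 0, R = 0)
  sums <- tapply(responses$assigned_score, responses$dimension, sum)
  out[names(sums)] <- sums
  pmax(out, 0)
}

#' Weighted total disability score
#'
#' Combines the four dimension totals into a single score,
#' \code{total = w_S * S + w_J * J + w_C * C + w_R * R}. By default each
#' dimension total is first rescaled to percent of its maximum attainable
#' score (0-100), so the weighted total also lies on a 0-100 scale on which
#' the default band edges (20/25/30) are meaningful. Set
#' \code{dimensionMax = NULL} to operate on raw point totals instead.
#'
#' @param dimScores named numeric vector \code{c(S, J, C, R)} (or an n x 4
#'   matrix of such rows) of non-negative dimension totals.
#' @param weights dimension weights, see \code{\link{defaultWeights}}.
#' @param dimensionMax per-dimension maxima used for rescaling (see
#'   \code{\link{dimensionMaxima}}), or \code{NULL} for raw totals.
#' @return numeric total score (vector if \code{dimScores} is a matrix).
#' @examples
#' totalScore(c(S = 11, J = 5, C = 14, R = 10))  # all maxima -> 100
#' totalScore(c(S = 5, J = 5, C = 5, R = 5), dimensionMax = NULL)  # 5
#' @export
totalScore <- function(dimScores, weights = defaultWeights(),
                       dimensionMax = dimensionMaxima()) {
  weights <- .checkWeights(weights)
  m <- if (is.matrix(dimScores)) dimScores else matrix(dimScores, nrow = 1)
  if (ncol(m) != 4) stop("dimScores must have 4 columns/elements (S, J, C, R)")
  if (is.null(colnames(m))) colnames(m) <- c("S", "J", "C", "R")
  m <- m[, c("S", "J", "C", "R"), drop = FALSE]
  if (anyNA(m) || any(m < 0)) stop("dimension scores must be non-negative")
  if (!is.null(dimensionMax)) {
    dm <- dimensionMax[c("S", "J", "C", "R")]
    if (anyNA(dm) || any(dm <= 0))
      stop("dimensionMax must supply positive S, J, C, R maxima")
    m <- sweep(m, 2, dm, "/") * 100
  }
  drop(m %*% weights)
}

#' Classify a total score into a disability state
#'
#' Applies the banded classification: totals at or below the severe edge are
#' state 4 (severe), then half-open 5-point bands give moderate (3) and mild
#' (2), and totals above the mild edge are healthy (1). The classification is
#' monotone: a higher total never maps to a more severe state.
#'
#' @param total numeric vector of non-negative total scores.
#' @param bands band edges, see \code{\link{defaultBands}}.
#' @return integer vector of state codes 1-4 (1 = healthy ... 4 = severe);
#'   labels via \code{stateLabels()[code]}.
#' @examples
#' classifyDisability(c(20, 23, 28, 40))  # 4 3 2 1
#' @export
classifyDisability <- function(total, bands = defaultBands()) {
  if (anyNA(total) || any(total < 0))
    stop("total scores must be non-negative and non-missing")
  if (length(bands) != 3 || any(diff(bands) <= 0))
    stop("bands must be 3 strictly increasing edges (severe, moderate, mild)")
  code <- ifelse(total <= bands[1], 4L,
          ifelse(total <= bands[2], 3L,
          ifelse(total <= bands[3], 2L, 1L)))
  as.integer(code)
}

#' Score, aggregate and classify a set of subjects
#'
#' Runs the full assessment for item-level response data: per-item scoring,
#' per-dimension aggregation, weighted total, and severity classification.
#' Subjects with vague responses (\code{"Not evaluated"}/\code{"Unclear"})
#' are removed (complete-case, the default) or their vague items replaced by
#' the modal score observed for that item (\code{impute = TRUE}).
#'
#' @param responses data.frame with columns \code{subject_id},
#'   \code{item_id}, \code{raw_option}.
#' @param scoreTable score table, see \code{\link{defaultScoreTable}}.
#' @param weights dimension weights.
#' @param bands severity band edges.
#' @param rescale rescale dimension totals to percent-of-maximum before
#'   weighting (default TRUE; see \code{\link{totalScore}}).
#' @param impute impute vague responses by the per-item modal score instead
#'   of dropping the subject.
#' @return data.frame with one row per retained subject: \code{subject_id},
#'   \code{s}, \code{j}, \code{c}, \code{r}, \code{total},
#'   \code{state_code}, \code{state_label}.
#' @export
scoreSubjects <- function(responses, scoreTable = defaultScoreTable(),
                          weights = defaultWeights(),
                          bands = defaultBands(),
                          rescale = TRUE, impute = FALSE) {
  need <- c("subject_id", "item_id", "raw_option")
  if (!all(need %in% names(responses)))
    stop("responses must have columns ", paste(need, collapse = ", "))
  if (nrow(responses) == 0) stop("no responses supplied")

  unknown <- setdiff(unique(responses$item_id), unique(scoreTable$item_id))
  if (length(unknown))
    stop("unknown item(s): ", paste(head(unknown, 5), collapse = ", "))
  key <- paste(scoreTable$item_id, scoreTable$option, sep = "\r")
  idx <- match(paste(responses$item_id, responses$raw_option, sep = "\r"), key)
  if (anyNA(idx)) {
    bad <- responses[is.na(idx), , drop = FALSE]
    stop("illegal option(s), e.g. '", bad$raw_option[1], "' for item '",
         bad$item_id[1], "'")
  }
  scored <- data.frame(subject_id = responses$subject_id,
                       dimension = scoreTable$dimension[idx],
                       item_id = responses$item_id,
                       assigned_score = scoreTable$score[idx],
                       stringsAsFactors = FALSE)

  vague <- is.na(scored$assigned_score)
  if (any(vague)) {
    if (impute) {
      for (it in unique(scored$item_id[vague])) {
        pool <- scored$assigned_score[scored$item_id == it & !vague]
        if (length(pool)) {
          tb <- table(pool)
          modal <- as.numeric(names(tb)[which.max(tb)])
          scored$assigned_score[vague & scored$item_id == it] <- modal
        }
      }
      vague <- is.na(scored$assigned_score)
    }
    dropIds <- unique(scored$subject_id[vague])
    if (length(dropIds)) {
      message("dropping ", length(dropIds),
              " subject(s) with vague responses (complete-case)")
      scored <- scored[!(scored$subject_id %in% dropIds), , drop = FALSE]
    }
  }
  if (nrow(scored) == 0) stop("all subjects removed as vague; nothing to score")

  ids <- unique(scored$subject_id)
  dims <- t(vapply(ids, function(id)
    aggregateDimensions(scored[scored$subject_id == id, , drop = FALSE]),
    numeric(4)))
  colnames(dims) <- c("S", "J", "C", "R")
  dimensionMax <- if (rescale) dimensionMaxima(scoreTable) else NULL
  tot <- totalScore(dims, weights = weights, dimensionMax = dimensionMax)
  code <- classifyDisability(tot, bands = bands)
  data.frame(subject_id = ids,
             s = dims[, "S"], j = dims[, "J"],
             c = dims[, "C"], r = dims[, "R"],
             total = tot, state_code = code,
             state_label = stateLabels()[code],
             stringsAsFactors = FALSE, row.names = NULL)
}
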