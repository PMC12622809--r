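test_that("item scoring maps options to their assigned points", {
  expect_equal(scoreItem("self_rated_health", "Very nice"), 4)
  expect_equal(scoreItem("self_rated_health", "Very bad"), 0)
  expect_equal(scoreItem("mmse_1", "Correct answer"), 1)
  expect_equal(scoreItem("adl_3", "Nothing to"), 1)
  expect_equal(scoreItem("memory_self", "Excellent"), 5)
  # disease item: 1 point, then one deduction per additional category
  expect_equal(scoreItem("disease_count", "0"), 1)
  expect_equal(scoreItem("disease_count", "1"), 0)
  expect_equal(scoreItem("disease_count", "3"), -2)
})

test_that("unknown items and illegal options fail; vague options flag removal", {
  expect_error(scoreItem("no_such_item", "Good"), "unknown item")
  expect_error(scoreItem("mmse_1", "Maybe"), "illegal option")
  expect_warning(out <- scoreItem("mmse_1", "Not evaluated"),
                 class = "removableRecord")
  expect_true(is.na(out))
})

test_that("dimension aggregation sums per dimension and floors at zero", {
  zero <- data.frame(dimension = c("S", "J", "C", "R"), assigned_score = 0)
  expect_equal(aggregateDimensions(zero), c(S = 0, J = 0, C = 0, R = 0))
  one <- data.frame(dimension = "S", assigned_score = 1)
  expect_equal(aggregateDimensions(one), c(S = 1, J = 0, C = 0, R = 0))
  # six-item fixture against hand addition: S = 1 + 0, J = 4 + (-2), C = 1, R = 3
  mixed <- data.frame(dimension = c("S", "S", "J", "J", "C", "R"),
                      assigned_score = c(1, 0, 4, -2, 1, 3))
  expect_equal(aggregateDimensions(mixed), c(S = 1, J = 2, C = 1, R = 3))
  # deductions never push a dimension below zero
  neg <- data.frame(dimension = "J", assigned_score = c(1, -4))
  expect_equal(aggregateDimensions(neg)[["J"]], 0)
  expect_error(aggregateDimensions(mixed[0, ]), "no scored")
  expect_error(aggregateDimensions(
    data.frame(dimension = "S", assigned_score = NA_real_)), "NA")
})

test_that("weighted total equals the direct multiply-add and keeps scale identities", {
  w <- defaultWeights()
  # weights sum to 1, so four equal dimension scores give that score back (raw)
  expect_equal(totalScore(c(S = 7, J = 7, C = 7, R = 7),
                          dimensionMax = NULL), 7)
  expect_equal(totalScore(c(S = 0, J = 0, C = 0, R = 0)), 0)
  expect_equal(totalScore(c(S = 10, J = 20, C = 5, R = 8),
                          dimensionMax = NULL),
               0.2513 * 10 + 0.3201 * 20 + 0.1968 * 5 + 0.2318 * 8)
  # percent-of-maximum rescaling: all maxima -> 100
  expect_equal(totalScore(dimensionMaxima()), 100)
  expect_error(totalScore(c(S = -1, J = 0, C = 0, R = 0)), "non-negative")
  expect_error(totalScore(c(S = 1, J = 1, C = 1, R = 1),
                          weights = c(0.5, 0.5, 0.5, 0.5)), "sum to 1")
})

test_that("classification follows the 5-point bands with half-open edges", {
  expect_equal(classifyDisability(20), 4L)   # at the severe edge
  expect_equal(classifyDisability(23), 3L)
  expect_equal(classifyDisability(28), 2L)   # one band beyond moderate
  expect_equal(classifyDisability(31), 1L)
  expect_equal(classifyDisability(20.5), 3L) # fractional totals are moderate
  expect_equal(classifyDisability(25), 3L)
  expect_equal(classifyDisability(30), 2L)
  expect_error(classifyDisability(-1), "non-negative")
})

test_that("classification is monotone and total: higher totals never more severe", {
  totals <- seq(0, 100, by = 0.25)
  codes <- classifyDisability(totals)
  expect_true(all(diff(codes) <= 0))          # severity non-increasing
  expect_true(all(codes %in% 1:4))            # every total gets a state
})

test_that("subject-level scoring classifies, drops vague records, or imputes", {
  resp <- generateItemResponses(c(1, 2, 3, 4), seed = 42)
  out <- scoreSubjects(resp)
  expect_equal(out$state_code, c(1L, 2L, 3L, 4L))
  expect_equal(out$state_label, stateLabels()[out$state_code])
  # make one subject vague: complete-case removal drops exactly that subject
  vague <- resp
  vague$raw_option[vague$subject_id == "S00002" &
                     vague$item_id == "mmse_1"] <- "Unclear"
  expect_message(out2 <- scoreSubjects(vague), "dropping 1 subject")
  expect_setdiff <- setdiff(out$subject_id, out2$subject_id)
  expect_equal(expect_setdiff, "S00002")
  # modal imputation keeps the subject
  out3 <- scoreSubjects(vague, impute = TRUE)
  expect_equal(nrow(out3), 4)
})
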