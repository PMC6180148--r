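test_that("loading a cohort parses scores, missing cells, and rejects bad input", {
  roster_path <- withr::local_tempfile(fileext = ".csv")
  scores_path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "dog_id,sex,breed,age_years,cohort,status_flags,outcome",
    "d1,female,lab,2.0,exploratory,,graduate",
    "d2,male,lab,1.8,exploratory,hearing_transfer,release",
    "d3,female,lab,2.1,exploratory,,graduate"), roster_path)
  writeLines(c(
    "dog_id,Odor Discrimination,arm pointing",
    "d1,1.5,2.0",
    "d2,,1.0",
    "d3,0.5,3.0"), scores_path)
  co <- load_cohort(roster_path, scores_path)
  expect_equal(nrow(co$roster), 3)
  expect_equal(rownames(co$scores), co$roster$dog_id)
  expect_equal(colnames(co$scores), c("odor discrimination", "arm pointing"))
  expect_equal(sum(is.na(co$scores)), 1)
  expect_true(is.na(co$scores["d2", "odor discrimination"]))

  # round trip preserves values, missingness, ordering
  r2 <- withr::local_tempfile(fileext = ".csv")
  s2 <- withr::local_tempfile(fileext = ".csv")
  write_cohort(co, r2, s2)
  co2 <- load_cohort(r2, s2)
  expect_identical(co2$scores, co$scores)
  expect_equal(co2$roster$dog_id, co$roster$dog_id)
  expect_equal(co2$roster$outcome, co$roster$outcome)

  # duplicate id names the offender
  writeLines(c(
    "dog_id,sex,breed,age_years,cohort,status_flags,outcome",
    "d1,female,lab,2.0,exploratory,,graduate",
    "d1,male,lab,1.8,exploratory,,release"), roster_path)
  expect_error(load_cohort(roster_path, scores_path), "d1")

  # non-numeric score cell names row and column
  writeLines(c(
    "dog_id,sex,breed,age_years,cohort,status_flags,outcome",
    "d1,female,lab,2.0,exploratory,,graduate"), roster_path)
  writeLines(c("dog_id,arm pointing", "d1,oops"), scores_path)
  expect_error(load_cohort(roster_path, scores_path), "arm pointing")

  # unknown measure names are errors, not dropped columns
  writeLines(c("dog_id,made-up task", "d1,1.0"), scores_path)
  expect_error(load_cohort(roster_path, scores_path), "made-up task")
})

test_that("measure vocabulary matching is case- and whitespace-insensitive", {
  expect_equal(normalize_measure_name("Memory — Distraction"),
               "memory-distraction")
  expect_equal(normalize_measure_name("  Laterality :  First Step "),
               "laterality: first step")
  expect_silent(check_measure_names(c("Unsolvable Task (look at experimenter)",
                                      "causal reasoning (visual)")))
  expect_error(check_measure_names("telepathy"), "telepathy")
})

make_roster <- function(n, flags = character(n), aborted = integer(n)) {
  data.frame(dog_id = sprintf("d%03d", seq_len(n)), sex = "female",
             breed = "lab", age_years = 2, cohort = "exploratory",
             status_flags = flags, aborted_tasks = aborted,
             outcome = NA_character_, stringsAsFactors = FALSE)
}

test_that("exclusion rules remove each dog once, in order, with exact accounting", {
  # composition mirroring an exploratory assistance-dog cohort:
  # 164 dogs, 21 program transfers, 24 task-aborters, 8 medical releases
  flags <- character(164)
  flags[1:21] <- "hearing_transfer"
  flags[22:29] <- "medical_release"
  aborted <- integer(164)
  aborted[30:53] <- 3
  roster <- make_roster(164, flags, aborted)
  scores <- matrix(rnorm(164 * 2), 164,
                   dimnames = list(roster$dog_id,
                                   c("cylinder", "arm pointing")))
  rules <- list(
    exclusion_rule("hearing transfer", "status_flag", "hearing_transfer"),
    exclusion_rule("aborted > 2 tasks", "max_aborted_tasks", 2),
    exclusion_rule("medical release", "status_flag", "medical_release"))
  res <- apply_exclusions(roster, scores, rules)
  expect_equal(res$report$initial_n, 164)
  expect_equal(unname(res$report$removed), c(21L, 24L, 8L))
  expect_equal(res$report$final_n, 111)
  expect_equal(nrow(res$scores), nrow(res$roster))
  expect_equal(rownames(res$scores), res$roster$dog_id)

  # a dog matching two rules is counted only under the first
  flags2 <- c("hearing_transfer;medical_release", "medical_release", "")
  roster2 <- make_roster(3, flags2)
  res2 <- apply_exclusions(roster2, scores[1:3, ], rules)
  expect_equal(unname(res2$report$removed), c(1L, 0L, 1L))
  expect_equal(res2$report$final_n, 1)

  # empty rule list is the identity
  res3 <- apply_exclusions(roster, scores, list())
  expect_equal(res3$report$final_n, 164)
  expect_length(res3$report$removed, 0)

  expect_error(exclusion_rule("bad", "status_flag", "not_a_flag"),
               "not_a_flag")
})

test_that("data-completeness exclusions use the missingness of the score matrix", {
  # prospective-cohort composition: 180 dogs, 33 status removals, 26 dogs
  # missing more than two predictor measures
  flags <- character(180)
  flags[1:19] <- "hearing_transfer"
  flags[20:24] <- "medical_release"
  flags[25:31] <- "other_program"
  flags[32:33] <- "in_training"
  roster <- make_roster(180, flags)
  scores <- matrix(rnorm(180 * 11), 180,
                   dimnames = list(roster$dog_id,
                                   rep(dctb_measures()[1:11])))
  scores[34:59, 1:3] <- NA  # 26 dogs with 3 missing predictors
  rules <- list(
    exclusion_rule("status", "status_flag",
                   c("hearing_transfer", "medical_release", "other_program",
                     "in_training")),
    exclusion_rule("missing > 2 predictors", "max_missing_predictors", 2))
  res <- apply_exclusions(roster, scores, rules)
  expect_equal(unname(res$report$removed), c(33L, 26L))
  expect_equal(res$report$final_n, 121)
})

test_that("missingness summary counts reconcile along both axes", {
  m <- toy_scores(5, 3)
  expect_true(all(missingness_summary(m)$per_dog == 0))
  m[2, 1] <- NA; m[4, c(1, 2, 3)] <- NA
  ms <- missingness_summary(m)
  expect_equal(sum(ms$per_dog), 4)
  expect_equal(sum(ms$per_measure), 4)
  expect_equal(unname(ms$per_dog[4]), 3)
  expect_equal(ms$total, 4)
})
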