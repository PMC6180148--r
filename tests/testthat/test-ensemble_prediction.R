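# A small planted-signal cohort used across several blocks.
planted_cohort <- function(n = 120, seed = 7) {
  cfg <- synthetic_config(
    n_dogs = n, seed = seed,
    outcome_coefficients = c("odor discrimination" = 1.2, "arm pointing" = 1.2))
  simulate_cohort(cfg, detection = FALSE)
}

test_that("threshold classification follows the documented tie rule", {
  expect_equal(classify_threshold(c(0.2, 0.8)), c("release", "graduate"))
  expect_equal(classify_threshold(0.5), "graduate")      # tie -> graduate
  expect_equal(classify_threshold(c(0, 0.01), threshold = 1e-9),
               c("release", "graduate"))
  expect_error(classify_threshold(1.2))
})

test_that("AUC equals brute-force concordant-pair counting", {
  probs <- c(0.9, 0.8, 0.6, 0.6, 0.3, 0.1)
  labels <- c(1, 0, 1, 0, 1, 0)
  expect_equal(auc_roc(probs, labels), oracle_auc_pairs(probs, labels))
  # perfectly ordered and fully tied edge cases
  expect_equal(auc_roc(c(0.1, 0.2, 0.8, 0.9), c(0, 0, 1, 1)), 1)
  expect_equal(auc_roc(rep(0.4, 6), c(1, 0, 1, 0, 1, 0)), 0.5)
  # invariant under strictly monotone transforms of the scores
  set.seed(20)
  p <- runif(30); y <- rbinom(30, 1, p)
  expect_equal(auc_roc(p, y), auc_roc(qlogis(p), y))
  expect_equal(auc_roc(p, y), oracle_auc_pairs(p, y))
  expect_error(auc_roc(p, rep(1, 30)), "both classes")
})

test_that("AUC agrees with an established ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(21)
  p <- round(runif(40), 2)  # rounding forces ties
  y <- rbinom(40, 1, 0.6)
  ref <- as.numeric(pROC::auc(pROC::roc(y, p, quiet = TRUE,
                                        direction = "<", levels = c(0, 1))))
  expect_equal(auc_roc(p, y), ref)
})

test_that("quartile accuracy partitions by predicted probability with ties going low", {
  # 8 hand-built dogs: quartile cut points at p25/p50/p75
  probs <- c(0.05, 0.10, 0.30, 0.40, 0.60, 0.70, 0.90, 0.95)
  truth <- c("release", "graduate", "release", "release",
             "graduate", "release", "graduate", "graduate")
  qa <- quartile_accuracy(probs, truth)
  expect_equal(qa$quartile, c(1L, 1L, 2L, 2L, 3L, 3L, 4L, 4L))
  # q1: predicted release twice, one truly release -> 0.5
  expect_equal(qa$q1_accuracy, 0.5)
  # q4: predicted graduate twice, both graduate -> 1
  expect_equal(qa$q4_accuracy, 1)

  # probabilities identical to 0/1 outcomes give perfect tail accuracy
  p01 <- c(0, 0, 0, 1, 1, 1, 0, 1)
  y01 <- c("release", "release", "release", "graduate", "graduate",
           "graduate", "release", "graduate")
  qa2 <- quartile_accuracy(p01, y01)
  expect_equal(qa2$q1_accuracy, 1)
  expect_equal(qa2$q4_accuracy, 1)

  # overall accuracy is the size-weighted mean of the quartile accuracies
  set.seed(31)
  p <- runif(40); y <- ifelse(rbinom(40, 1, p) == 1, "graduate", "release")
  q <- quartile_accuracy(p, y)
  lab <- classify_threshold(p)
  accs <- vapply(1:4, function(k) mean((lab == y)[q$quartile == k]), numeric(1))
  wts <- tabulate(q$quartile, 4) / 40
  expect_equal(sum(accs * wts), mean(lab == y))

  expect_error(quartile_accuracy(rep(0.5, 10), rep(c("graduate", "release"), 5)),
               "identical")
  expect_error(quartile_accuracy(c(0.1, 0.9), c("graduate", "release")),
               "at least 8")
})

test_that("importance scaling maps each family to [0, 100] linearly", {
  raw <- rbind(GLM = c(1, 2, 3), RF = c(10, 110, 60))
  sc <- scale_importance(raw)
  expect_equal(unname(sc["GLM", ]), c(0, 50, 100))
  expect_equal(unname(sc["RF", ]), c(0, 100, 50))
  # invariant to positive affine transforms of the raws
  expect_equal(scale_importance(raw * 3.7 + 11), sc)
  expect_warning(flat <- scale_importance(rbind(NB = c(2, 2, 2))), "NB")
  expect_equal(unname(flat[1, ]), c(0, 0, 0))
})

test_that("the graduate-vs-release probability test matches the Welch oracle", {
  a <- c(0.81, 0.74, 0.69, 0.88, 0.60)  # graduates
  b <- c(0.55, 0.48, 0.71, 0.50, 0.62)  # releases
  probs <- c(a, b)
  outc <- rep(c("graduate", "release"), each = 5)
  got <- group_probability_ttest(probs, outc)
  want <- oracle_welch(a, b)
  expect_equal(got$t, want$t)
  expect_equal(got$df, want$df)          # fractional Welch df
  expect_equal(got$p, want$p_greater)
  # identical distributions: t = 0, one-tailed p = 0.5
  same <- rep(c(0.4, 0.6, 0.5), 2)
  null <- group_probability_ttest(same, rep(c("graduate", "release"), each = 3))
  expect_equal(null$t, 0)
  expect_equal(null$p, 0.5)
  # q1-and-q4 restriction keeps about half the dogs
  set.seed(41)
  p <- runif(40); y <- ifelse(rbinom(40, 1, 0.6) == 1, "graduate", "release")
  restricted <- group_probability_ttest(p, y, "q1_and_q4")
  expect_equal(restricted$n_graduate + restricted$n_release, 20)
  expect_error(group_probability_ttest(c(0.2, 0.8), c("graduate", "release")))
})

test_that("univariate screening ranks a planted predictor first and skips constants", {
  co <- planted_cohort(n = 150, seed = 13)
  scores <- cbind(co$scores,
                  "retrieval" = rep(1, 150))  # constant, must be skipped
  expect_warning(res <- univariate_screen(scores, co$roster$outcome),
                 "retrieval")
  expect_false("retrieval" %in% res$measure)
  expect_equal(res$rank, seq_len(nrow(res)))
  expect_equal(res$p_value, sort(res$p_value))
  # the two planted measures carry the signal; the strongest must lead
  expect_true(res$measure[1] %in% c("odor discrimination", "arm pointing"))
  expect_true(all(c("odor discrimination", "arm pointing") %in%
                    res$measure[1:3]))
})

test_that("repeated CV covers every dog out-of-fold once per repeat and is seed-deterministic", {
  co <- planted_cohort(n = 48, seed = 3)
  sc <- co$scores
  scheme <- cv_scheme(folds = 4, repeats = 3, seed = 99)
  r1 <- repeated_cv(sc, co$roster$outcome, model_config("GLM"), scheme)
  expect_equal(nrow(r1$iterations), 12)
  # per repeat the four test folds partition the cohort
  expect_equal(as.vector(tapply(r1$iterations$n_test,
                                r1$iterations$repeat_index, sum)),
               rep(48, 3))
  # stratification keeps the class ratio within one dog per fold
  y <- factor(co$roster$outcome)
  set.seed(scheme$seed)
  assign <- caninecog:::make_folds(y, 4, TRUE)
  per_fold <- table(assign, y)
  expect_lte(diff(range(per_fold[, "graduate"])), 1)
  expect_lte(diff(range(per_fold[, "release"])), 1)
  # byte-identical rerun from the same seed
  r2 <- repeated_cv(sc, co$roster$outcome, model_config("GLM"), scheme)
  expect_identical(r1$iterations, r2$iterations)
  # a different seed changes the splits
  r3 <- repeated_cv(sc, co$roster$outcome, model_config("GLM"),
                    cv_scheme(folds = 4, repeats = 3, seed = 100))
  expect_false(identical(r1$iterations$accuracy, r3$iterations$accuracy))
})

test_that("CV metrics equal an independent re-fit of the same splits (GLM oracle)", {
  co <- planted_cohort(n = 32, seed = 17)
  sc <- co$scores
  y <- factor(co$roster$outcome, levels = c("release", "graduate"))
  scheme <- cv_scheme(folds = 4, repeats = 1, seed = 5)
  got <- repeated_cv(sc, co$roster$outcome, model_config("GLM"), scheme)
  # reconstruct the same fold assignment, then re-fit outside the harness
  set.seed(scheme$seed)
  assign <- caninecog:::make_folds(y, 4, TRUE)
  for (f in 1:4) {
    test <- which(assign == f)
    df <- data.frame(y = as.numeric(y == "graduate"), sc, check.names = TRUE)
    fit <- suppressWarnings(glm(y ~ ., data = df[-test, ], binomial))
    p <- predict(fit, newdata = df[test, ], type = "response")
    acc <- mean(ifelse(p >= 0.5, "graduate", "release") ==
                  as.character(y[test]))
    row <- got$iterations[got$iterations$fold == f, ]
    expect_equal(row$accuracy, acc)
    expect_equal(row$auc, oracle_auc_pairs(unname(p),
                                           as.numeric(y[test] == "graduate")))
  }
})

test_that("separable data are learned and label-independent data are not", {
  co <- planted_cohort(n = 100, seed = 23)
  # perfectly separable: one measure equals the outcome indicator
  sep <- co$scores
  sep[, 1] <- as.numeric(co$roster$outcome == "graduate") * 10
  r <- repeated_cv(sep, co$roster$outcome, model_config("KNN"),
                   cv_scheme(4, 2, seed = 1))
  expect_gte(r$summary$accuracy, 0.95)
  # null cohort: labels independent of all measures; few predictors relative
  # to n so the small-sample pessimism of out-of-fold AUC stays negligible
  null_cfg <- synthetic_config(n_dogs = 200, seed = 29,
                               measure_names = c("cylinder", "retrieval",
                                                 "rotation"),
                               n_factors = 1)
  nc <- simulate_cohort(null_cfg, detection = FALSE)
  rn <- repeated_cv(nc$scores, nc$roster$outcome, model_config("GLM"),
                    cv_scheme(4, 20, seed = 2))
  expect_lt(abs(mean(rn$iterations$auc, na.rm = TRUE) - 0.5), 0.05)
})

test_that("every family fits, predicts in [0,1], and freezes for a new cohort", {
  co <- planted_cohort(n = 90, seed = 37)
  ens <- fit_ensemble(co$scores, co$roster$outcome, seed = 2)
  expect_setequal(rownames(ens$importance),
                  c("GLM", "LDA", "RR", "PLS", "NB", "MARS", "KNN", "RF"))
  expect_true(all(ens$importance >= 0 & ens$importance <= 100))
  expect_true(all(apply(ens$importance, 1, max) == 100))
  expect_true(all(apply(ens$importance, 1, min) == 0))

  new_co <- planted_cohort(n = 40, seed = 38)
  probs <- predict_ensemble(ens, new_co$scores)
  expect_equal(dim(probs), c(40, 8))
  expect_true(all(probs >= 0 & probs <= 1))
  # frozen models reject a cohort missing a required measure, naming it
  expect_error(predict_ensemble(ens, new_co$scores[, -1]),
               colnames(co$scores)[1], fixed = TRUE)
  # planted signal transfers: ensemble-mean probability discriminates
  truth <- new_co$roster$outcome
  expect_gt(auc_roc(rowMeans(probs), truth), 0.6)
})
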