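test_that("two-group associations carry the direction of the performance contrast", {
  set.seed(51)
  # above-average performers score clearly higher on the cognitive measure
  g <- factor(rep(c("below", "above"), each = 15),
              levels = c("below", "above"), ordered = TRUE)
  x <- c(rnorm(15, 0), rnorm(15, 3))
  rec <- test_association(x, g)
  expect_true(rec$significant)
  expect_equal(rec$direction, "positive")
  rec_neg <- test_association(-x, g)
  expect_equal(rec_neg$direction, "negative")
  # identical distributions are not significant
  same <- test_association(rep(c(1, 2, 3), 10), g)
  expect_false(same$significant)
  expect_equal(same$direction, "none")
  # a category emptied by missingness marks the record unavailable
  x_na <- x; x_na[g == "below"] <- NA
  expect_false(test_association(x_na, g)$available)
})

test_that("three-group associations are neutral when group means are non-monotone", {
  g3 <- factor(rep(c("below", "average", "above"), each = 12),
               levels = c("below", "average", "above"), ordered = TRUE)
  set.seed(52)
  # means approximately (1, 5, 1): significant omnibus but no direction
  x_bump <- c(rnorm(12, 1, 0.5), rnorm(12, 5, 0.5), rnorm(12, 1, 0.5))
  rec <- test_association(x_bump, g3)
  expect_true(rec$significant)
  expect_equal(rec$test, "anova_3group")
  expect_equal(rec$direction, "neutral")
  # monotone means get a direction
  x_mono <- c(rnorm(12, 0, 0.5), rnorm(12, 1.5, 0.5), rnorm(12, 3, 0.5))
  expect_equal(test_association(x_mono, g3)$direction, "positive")
  expect_equal(test_association(-x_mono, g3)$direction, "negative")
})

test_that("aggregate rows reconcile and match hand-tabulated counts", {
  counts <- detection_screen_counts()
  agg <- aggregate_from_counts(counts)
  # arithmetic identities on every row
  expect_true(all(agg$total ==
                    agg$n_positive + agg$n_negative + agg$n_neutral))
  expect_true(all(agg$aggregate == agg$n_positive - agg$n_negative))
  expect_true(all(abs(agg$aggregate) <= agg$total))
  pick <- function(m) agg$aggregate[agg$cognitive_measure == m]
  expect_equal(pick("odor discrimination"), 5)
  expect_equal(pick("transparent obstacle"), -1)
  expect_equal(pick("unsolvable task (manipulate container)"), -6)
  bad <- counts; bad$total[1] <- 99
  expect_error(aggregate_from_counts(bad), "reconcile")
})

test_that("build_aggregate_table counts only significant records and rejects duplicates", {
  rec <- data.frame(
    cognitive_measure = c("a", "a", "a", "b", "b"),
    performance_measure = c("p1", "p2", "p3", "p1", "p2"),
    significant = c(TRUE, TRUE, FALSE, TRUE, TRUE),
    direction = c("positive", "negative", "positive", "neutral", "positive"),
    stringsAsFactors = FALSE)
  agg <- build_aggregate_table(rec)
  a <- agg[agg$cognitive_measure == "a", ]
  expect_equal(a$total, 2)        # the non-significant row does not count
  expect_equal(a$aggregate, 0)
  b <- agg[agg$cognitive_measure == "b", ]
  expect_equal(b$n_neutral, 1)
  expect_equal(b$aggregate, 1)
  expect_error(build_aggregate_table(rbind(rec, rec[1, ])), "duplicate")
})

test_that("the consensus null test reproduces the published summary arithmetic", {
  agg <- aggregate_from_counts(detection_screen_counts())
  cs <- consensus_null_test(agg)
  expect_equal(cs$n_measures, 29)
  expect_equal(cs$df, 28)
  expect_equal(round(cs$t, 2), 0.86)
  expect_equal(round(cs$p, 2), 0.40)
  expect_equal(round(cs$mean_aggregate, 1), 0.4)
  expect_equal(round(cs$sem_aggregate, 1), 0.4)
  expect_equal(round(cs$mean_associations, 1), 3.2)
  expect_equal(round(cs$sem_associations, 1), 0.4)
  # symmetric aggregates give t exactly 0
  sym <- data.frame(aggregate = c(-2, -1, 0, 1, 2), total = rep(2, 5))
  expect_equal(consensus_null_test(sym)$t, 0)
  # a one-sample t oracle on the same numbers
  want <- oracle_one_sample_t(agg$aggregate)
  expect_equal(cs$t, want$t)
  expect_equal(cs$p, want$p_two)
  expect_error(consensus_null_test(data.frame(aggregate = c(1, 1),
                                              total = c(1, 1))), "identical")
})

test_that("short-battery selection applies the |aggregate| threshold plus manual includes", {
  agg <- aggregate_from_counts(detection_screen_counts())
  sel <- select_short_battery(agg, threshold = 3)
  expect_setequal(sel$cognitive_measure,
                  c("marker cue", "odor discrimination", "arm pointing",
                    "causal reasoning (visual)", "working memory",
                    "memory-distraction",
                    "unsolvable task (manipulate container)"))
  expect_setequal(sel$aggregate, c(5, 5, 4, 4, 3, 3, -6))
  # a manually retained simple measure is flagged as such
  sel2 <- select_short_battery(agg, 3, "laterality: object manipulation")
  expect_equal(sel2$reason[sel2$cognitive_measure ==
                             "laterality: object manipulation"], "manual")
  expect_equal(nrow(sel2), 8)
  # threshold above the observed maximum empties the rule-based selection
  expect_equal(nrow(select_short_battery(agg, 7)), 0)
  # threshold 1 keeps exactly the rows with non-zero aggregate
  expect_equal(nrow(select_short_battery(agg, 1)),
               sum(agg$aggregate != 0))
  expect_error(select_short_battery(agg, 3, "telepathy"), "telepathy")
})

test_that("orientation flips reverse every association direction with that measure", {
  set.seed(53)
  n <- 80
  quality <- rnorm(n)
  cog <- cbind("arm pointing" = 0.7 * quality + 0.5 * rnorm(n),
               "cylinder" = rnorm(n))
  rownames(cog) <- sprintf("dog_%03d", 1:n)
  perf <- cbind(speed = quality + 0.3 * rnorm(n))
  rownames(perf) <- rownames(cog)
  g_up <- association_grid(cog, perf, n_categories = 2)
  g_down <- association_grid(cog, -perf, n_categories = 2)
  sig <- g_up$significant
  expect_true(any(sig))
  flip <- c(positive = "negative", negative = "positive", none = "none",
            neutral = "neutral")
  expect_equal(unname(flip[g_up$direction[sig]]), g_down$direction[sig])
})
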