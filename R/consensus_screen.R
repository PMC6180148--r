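# Directional consensus screening: per-pair association tests between a
# cognitive measure and a discretized performance measure, +1/0/-1
# annotation, the per-measure aggregate score, its sign-randomness null test,
# and short-battery selection.
#
# The screen deliberately applies no multiple-testing correction: with a
# large grid of tests many false positives are expected, but their direction
# should be random, so only measures with a consistent directional consensus
# (large |aggregate|) stand out.

#' Test one cognitive measure against one discretized performance measure
#'
#' With two performance categories, a two-sample t-test (Welch by default)
#' compares cognition scores between the below- and above-average groups; the
#' association is positive when the above-average-performance group has the
#' higher mean cognition score. With three categories, a one-way ANOVA is
#' used; a significant omnibus test is annotated positive or negative only
#' when the ordered group means are weakly monotone (ties allowed at one
#' junction), and neutral otherwise — e.g. when the below and above groups
#' are similar but the middle group deviates.
#'
#' @param cog_scores numeric cognition scores, one per dog (`NA` allowed).
#' @param categories ordered factor from [discretize_quantiles()], aligned
#'   with `cog_scores`.
#' @param alpha significance level (default 0.05, uncorrected by design).
#' @param pooled_variance use the pooled-variance t-test instead of Welch.
#' @return data.frame row with `test`, `p_value`, `significant`, `direction`
#'   (`positive`/`negative`/`neutral`), `n_used`, `available`.
#' @export
test_association <- function(cog_scores, categories, alpha = 0.05,
                             pooled_variance = FALSE) {
  ok <- is.finite(cog_scores) & !is.na(categories)
  x <- cog_scores[ok]
  g <- droplevels(factor(categories[ok],
                         levels = levels(categories), ordered = TRUE))
  unavailable <- data.frame(test = NA_character_, p_value = NA_real_,
                            significant = FALSE, direction = "none",
                            n_used = length(x), available = FALSE,
                            stringsAsFactors = FALSE)
  n_cat <- nlevels(categories)
  if (nlevels(g) < n_cat || any(table(g) < 2)) return(unavailable)
  means <- tapply(x, g, mean)
  if (n_cat == 2) {
    if (any(tapply(x, g, stats::sd) == 0) && length(unique(x)) == 1)
      return(unavailable)
    tt <- stats::t.test(x ~ g, var.equal = pooled_variance)
    p <- tt$p.value
    dir <- if (p < alpha) {
      if (means[[2]] > means[[1]]) "positive" else "negative"
    } else "none"
    data.frame(test = "two_sample_t", p_value = p, significant = p < alpha,
               direction = dir, n_used = length(x), available = TRUE,
               stringsAsFactors = FALSE)
  } else {
    if (length(unique(x)) == 1) return(unavailable)
    p <- summary(stats::aov(x ~ g))[[1]][["Pr(>F)"]][1]
    dir <- "none"
    if (p < alpha) {
      d <- diff(means)
      monotone <- all(d >= 0) || all(d <= 0)
      dir <- if (monotone && means[[n_cat]] != means[[1]]) {
        if (means[[n_cat]] > means[[1]]) "positive" else "negative"
      } else "neutral"
    }
    data.frame(test = "anova_3group", p_value = p, significant = p < alpha,
               direction = dir, n_used = length(x), available = TRUE,
               stringsAsFactors = FALSE)
  }
}

#' Run the full cognition x performance association grid
#'
#' Discretizes each performance measure into quantile categories and tests
#' every cognitive measure against it. Performance values must already be
#' orientation-normalized (see [assemble_performance_table()]) so that
#' "positive" uniformly means higher cognition scores go with better
#' performance.
#'
#' @param cognition dogs x cognitive-measures numeric matrix (`NA` allowed).
#' @param performance a `performance_table` or a dogs x measures matrix of
#'   orientation-normalized performance values.
#' @param n_categories named integer vector (2 or 3) per performance measure,
#'   or a single value recycled to all measures (default 2).
#' @param alpha significance level.
#' @param pooled_variance passed to [test_association()].
#' @return long data.frame with one row per (cognitive, performance) pair.
#' @export
association_grid <- function(cognition, performance, n_categories = 2,
                             alpha = 0.05, pooled_variance = FALSE) {
  perf <- if (inherits(performance, "performance_table")) performance$values
          else performance
  if (length(n_categories) == 1)
    n_categories <- stats::setNames(rep(n_categories, ncol(perf)),
                                    colnames(perf))
  dogs <- intersect(rownames(cognition), rownames(perf))
  if (length(dogs) == 0) stop("no shared dogs between cognition and performance")
  rows <- list()
  for (pm in colnames(perf)) {
    pv <- perf[dogs, pm]
    cat_vec <- tryCatch(
      discretize_quantiles(pv, n_categories[[pm]]),
      error = function(e) NULL)
    for (cm in colnames(cognition)) {
      rec <- if (is.null(cat_vec)) {
        data.frame(test = NA_character_, p_value = NA_real_,
                   significant = FALSE, direction = "none", n_used = 0L,
                   available = FALSE, stringsAsFactors = FALSE)
      } else {
        test_association(cognition[dogs, cm], cat_vec, alpha = alpha,
                         pooled_variance = pooled_variance)
      }
      rows[[length(rows) + 1]] <- cbind(
        data.frame(cognitive_measure = cm, performance_measure = pm,
                   stringsAsFactors = FALSE), rec)
    }
  }
  do.call(rbind, rows)
}

#' Aggregate directional association counts per cognitive measure
#'
#' Counts, among significant associations only, how many are positive,
#' negative, and neutral for each cognitive measure, and forms the aggregate
#' score `n_positive - n_negative` (neutral contributes 0). A measure
#' significantly associated with six performance measures, all positively,
#' scores +6; three positive and three negative cancel to 0.
#'
#' @param records long data.frame from [association_grid()] (columns
#'   `cognitive_measure`, `performance_measure`, `significant`, `direction`).
#' @return data.frame with columns `cognitive_measure`, `total`, `n_negative`,
#'   `n_neutral`, `n_positive`, `aggregate`.
#' @export
build_aggregate_table <- function(records) {
  key <- paste(records$cognitive_measure, records$performance_measure)
  if (anyDuplicated(key))
    stop("duplicate (cognitive, performance) pair(s): ",
         paste(unique(key[duplicated(key)]), collapse = ", "))
  measures <- unique(records$cognitive_measure)
  out <- lapply(measures, function(m) {
    r <- records[records$cognitive_measure == m & records$significant, ,
                 drop = FALSE]
    np <- sum(r$direction == "positive")
    nn <- sum(r$direction == "negative")
    nz <- sum(r$direction == "neutral")
    data.frame(cognitive_measure = m, total = np + nn + nz,
               n_negative = nn, n_neutral = nz, n_positive = np,
               aggregate = np - nn, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out[order(-out$aggregate, out$cognitive_measure), , drop = FALSE]
}

#' Aggregate scores from pre-tabulated association counts
#'
#' For count tables published as total/negative/neutral/positive columns
#' (rather than raw per-pair records): recomputes the aggregate as
#' `positive - negative` and checks the counts reconcile.
#'
#' @param counts data.frame with columns `cognitive_measure` (or `measure`),
#'   `total`, `n_negative`/`negative`, `n_neutral`/`neutral`,
#'   `n_positive`/`positive`.
#' @return data.frame in the [build_aggregate_table()] layout.
#' @export
aggregate_from_counts <- function(counts) {
  pick <- function(...) {
    for (nm in c(...)) if (nm %in% names(counts)) return(counts[[nm]])
    stop("counts table lacks a '", ..1, "' column")
  }
  out <- data.frame(
    cognitive_measure = as.character(pick("cognitive_measure", "measure")),
    total = pick("total"),
    n_negative = pick("n_negative", "negative"),
    n_neutral = pick("n_neutral", "neutral"),
    n_positive = pick("n_positive", "positive"),
    stringsAsFactors = FALSE)
  if (any(out$total != out$n_negative + out$n_neutral + out$n_positive))
    stop("association counts do not reconcile with totals")
  out$aggregate <- out$n_positive - out$n_negative
  out
}

#' Test whether aggregate scores are centred on zero
#'
#' Under the screen's null logic — false positives equally likely to be
#' positive or negative — the per-measure aggregate scores should have mean
#' zero. This runs a two-tailed one-sample t-test of the aggregates against
#' 0 and also summarises the per-measure counts of significant associations.
#'
#' @param rows aggregate table from [build_aggregate_table()] or
#'   [aggregate_from_counts()].
#' @return list with `mean_aggregate`, `sem_aggregate`, `t`, `df`, `p`,
#'   `mean_associations`, `sem_associations`, `n_measures`.
#' @export
consensus_null_test <- function(rows) {
  agg <- rows$aggregate
  if (length(agg) < 2) stop("need at least 2 cognitive measures")
  if (stats::sd(agg) == 0) stop("all aggregate scores identical: zero variance")
  tt <- stats::t.test(agg, mu = 0)
  tot <- rows$total
  list(mean_aggregate = mean(agg),
       sem_aggregate = stats::sd(agg) / sqrt(length(agg)),
       t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value,
       mean_associations = mean(tot),
       sem_associations = stats::sd(tot) / sqrt(length(tot)),
       n_measures = length(agg))
}

#' Select measures for a short-format battery
#'
#' Retains every cognitive measure whose aggregate score reaches the
#' threshold in absolute value, plus any manually included measures (flagged
#' as such — e.g. a simple, quick task kept for practical utility despite a
#' weak aggregate).
#'
#' @param rows aggregate table.
#' @param threshold minimum `|aggregate|` for rule-based selection
#'   (default 3).
#' @param manual_includes character vector of measure names to force in.
#' @return data.frame with `cognitive_measure`, `aggregate`, `reason`
#'   (`"aggregate"` or `"manual"`).
#' @export
select_short_battery <- function(rows, threshold = 3,
                                 manual_includes = character(0)) {
  if (threshold < 1) stop("threshold must be >= 1")
  unknown <- setdiff(manual_includes, rows$cognitive_measure)
  if (length(unknown) > 0)
    stop("manual include names unknown measure(s): ",
         paste(unknown, collapse = ", "))
  by_rule <- rows[abs(rows$aggregate) >= threshold, , drop = FALSE]
  sel <- data.frame(cognitive_measure = by_rule$cognitive_measure,
                    aggregate = by_rule$aggregate,
                    reason = rep("aggregate", nrow(by_rule)),
                    stringsAsFactors = FALSE)
  manual <- setdiff(manual_includes, sel$cognitive_measure)
  if (length(manual) > 0) {
    idx <- match(manual, rows$cognitive_measure)
    sel <- rbind(sel, data.frame(cognitive_measure = manual,
                                 aggregate = rows$aggregate[idx],
                                 reason = "manual", stringsAsFactors = FALSE))
  }
  rownames(sel) <- NULL
  sel
}
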