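# Detection-dog performance measures: training-log ratio scores, duration
# adjustment, weighted ordinal rating scores, post-deployment pass rates, and
# assembly into one per-dog performance table.

#' The seven training-log behavioural categories
#' @return character vector of category names.
#' @export
log_categories <- function() {
  c("handling", "temperament", "motivation", "handler_dependence",
    "odor_recognition", "odor_response", "false_responses")
}

#' Score weekly training logs into per-category ratio scores
#'
#' Each weekly log assigns every behavioural category a prevalence score in
#' 0-3 (0 = no deficiency noted, 3 = consistent pattern of deficiency).
#' Weeks reporting 2 or fewer days of training are excluded entirely — from
#' both numerator and denominator. The ratio score per dog and category is
#' the sum of prevalence scores over eligible weeks divided by the number of
#' eligible weeks, so higher ratios mean more problems in training.
#'
#' @param logs data.frame with columns `dog_id`, `week_index`, `days_reported`
#'   and one column per category in [log_categories()].
#' @param min_days minimum days reported for a week to be scored (default 3).
#' @return data.frame with columns `dog_id`, `category`, `ratio`,
#'   `weeks_scored`; dogs with no eligible week are absent.
#' @export
score_training_logs <- function(logs, min_days = 3) {
  cats <- log_categories()
  miss <- setdiff(c("dog_id", "week_index", "days_reported", cats),
                  names(logs))
  if (length(miss) > 0)
    stop("training log is missing column(s): ", paste(miss, collapse = ", "))
  for (cat in cats) {
    v <- logs[[cat]]
    if (any(!is.na(v) & (v < 0 | v > 3 | v != round(v))))
      stop("prevalence scores must be integers in 0..3 (column '", cat, "')")
  }
  eligible <- logs[logs$days_reported >= min_days, , drop = FALSE]
  out <- list()
  for (id in unique(logs$dog_id)) {
    wk <- eligible[eligible$dog_id == id, , drop = FALSE]
    if (nrow(wk) == 0) next
    for (cat in cats) {
      out[[length(out) + 1]] <- data.frame(
        dog_id = id, category = cat,
        ratio = sum(wk[[cat]]) / nrow(wk),
        weeks_scored = nrow(wk), stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Adjust ratio scores for the amount of available data
#'
#' Ratio scores can be confounded with how long a dog was observed. This
#' regresses the ratio on the number of scored weeks by ordinary least
#' squares and returns the residuals multiplied by -1, so that higher
#' adjusted values correspond to better performance. Adjusted scores sum to
#' zero and are uncorrelated with `weeks_scored`.
#'
#' @param ratios numeric vector of per-dog ratio scores.
#' @param weeks_scored integer vector of per-dog scored-week counts.
#' @param center_only if `TRUE`, fall back to `-(ratio - mean)` when
#'   `weeks_scored` is constant instead of erroring.
#' @return numeric vector of adjusted scores (higher = better).
#' @export
adjust_for_duration <- function(ratios, weeks_scored, center_only = FALSE) {
  if (length(ratios) < 3) stop("need at least 3 dogs")
  if (length(ratios) != length(weeks_scored))
    stop("ratios and weeks_scored must have the same length")
  if (stats::sd(weeks_scored) == 0) {
    if (!center_only)
      stop("weeks_scored is constant: slope unidentifiable ",
           "(set center_only = TRUE to mean-center instead)")
    return(-(ratios - mean(ratios)))
  }
  -unname(stats::residuals(stats::lm(ratios ~ weeks_scored)))
}

#' Weighted score for a series of ordinal performance ratings
#'
#' Summarises a series of excellent/good/fair/poor ratings as
#' `sum(percent of records at each rating * weight)`, with percentages on a
#' 0-100 scale, so the score is bounded by 0 (all poor) and 100
#' (all excellent).
#'
#' @param ratings character vector of ratings.
#' @param weights named numeric vector of weights per rating; the default is
#'   `c(excellent = 1, good = 0.66, fair = 0.33, poor = 0)`.
#' @return numeric score in \[0, 100\].
#' @export
weighted_ordinal_score <- function(ratings,
                                   weights = c(excellent = 1, good = 0.66,
                                               fair = 0.33, poor = 0)) {
  if (length(ratings) == 0) stop("empty rating series")
  bad <- setdiff(unique(ratings), names(weights))
  if (length(bad) > 0)
    stop("unknown rating token(s): ", paste(bad, collapse = ", "))
  pct <- 100 * table(factor(ratings, levels = names(weights))) / length(ratings)
  sum(as.numeric(pct) * weights)
}

#' Percent of passed items per evaluation category
#'
#' @param passed,total non-negative integer vectors (same length, optionally
#'   named by category); `passed <= total`, `total >= 1`.
#' @return numeric vector of percentages in \[0, 100\].
#' @export
percent_passed <- function(passed, total) {
  if (length(passed) != length(total)) stop("length mismatch")
  if (any(total < 1)) stop("each category needs at least 1 item")
  if (any(passed > total)) stop("passed count exceeds total")
  if (any(passed < 0)) stop("negative passed count")
  100 * passed / total
}

#' Assemble per-dog performance measures into one wide table
#'
#' Takes any number of scored sources (each a data.frame with `dog_id`,
#' `measure`, `value`) together with an orientation map declaring, per
#' measure, whether larger values mean better performance. Measures declared
#' lower-is-better are sign-flipped when `normalize = TRUE`, so that in the
#' assembled table a positive association uniformly means "higher cognition
#' score, better performance". Cells with no source record stay `NA`
#' (the availability mask).
#'
#' @param sources list of data.frames with columns `dog_id`, `measure`,
#'   `value`.
#' @param orientation named logical vector: `TRUE` if higher raw values mean
#'   better performance, one entry per measure.
#' @param normalize flip lower-is-better measures (default `TRUE`).
#' @return a `performance_table`: list with `values` (dogs x measures numeric
#'   matrix, `NA` = unavailable), `orientation`, and `normalized`.
#' @export
assemble_performance_table <- function(sources, orientation,
                                       normalize = TRUE) {
  long <- do.call(rbind, lapply(sources, function(s) {
    stopifnot(all(c("dog_id", "measure", "value") %in% names(s)))
    s[, c("dog_id", "measure", "value")]
  }))
  if (nrow(long) == 0) stop("no performance records supplied")
  key <- paste(long$dog_id, long$measure, sep = "\r")
  dup <- duplicated(key)
  if (any(dup)) {
    conflicts <- key %in% key[dup]
    agg <- tapply(long$value[conflicts], key[conflicts],
                  function(v) length(unique(v)))
    if (any(agg > 1))
      stop("conflicting duplicate entries for dog/measure pair(s): ",
           paste(gsub("\r", " / ", names(agg)[agg > 1]), collapse = ", "))
    long <- long[!dup, , drop = FALSE]
  }
  measures <- unique(long$measure)
  miss_or <- setdiff(measures, names(orientation))
  if (length(miss_or) > 0)
    stop("no orientation declared for measure(s): ",
         paste(miss_or, collapse = ", "))
  dogs <- unique(long$dog_id)
  values <- matrix(NA_real_, length(dogs), length(measures),
                   dimnames = list(dogs, measures))
  values[cbind(match(long$dog_id, dogs), match(long$measure, measures))] <-
    long$value
  if (normalize) {
    flip <- measures[!orientation[measures]]
    values[, flip] <- -values[, flip]
  }
  structure(list(values = values,
                 orientation = orientation[measures],
                 normalized = isTRUE(normalize)),
            class = "performance_table")
}

#' @export
print.performance_table <- function(x, ...) {
  cat(sprintf("Performance table: %d dogs x %d measures (%.0f%% cells available%s)\n",
              nrow(x$values), ncol(x$values),
              100 * mean(is.finite(x$values)),
              if (x$normalized) ", orientation-normalized" else ""))
  invisible(x)
}
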