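# End-to-end workflows: the two-cohort predictive-modelling experiment and
# the consensus-screen + replication experiment, each returning a structured
# report with a run manifest.

run_manifest <- function(seed, config) {
  list(seed = seed, config = config,
       package_version = as.character(utils::packageVersion("caninecog")),
       timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
}

#' Exploratory-then-prospective predictive modelling workflow
#'
#' Fits the classifier ensemble on an exploratory cohort with repeated
#' stratified cross-validation, freezes the fitted preprocessing (Box-Cox
#' transforms) and models, and applies them unchanged to an independent
#' prediction cohort. Reports per-family CV metrics, scaled variable
#' importances, univariate screening ranks, prediction-cohort metrics
#' (AUC, accuracy, upper-quartile accuracy), and one-tailed Welch t-tests
#' comparing predicted probabilities of graduates vs releases.
#'
#' @param exploratory list with `scores` (dogs x measures matrix) and
#'   `outcomes` (`"graduate"`/`"release"` per dog).
#' @param prediction optional list in the same layout for the independent
#'   cohort; `NULL` skips the prospective stage.
#' @param families model families to run (default all eight).
#' @param scheme a [cv_scheme()].
#' @param impute_k neighbours for kNN imputation.
#' @param boxcox apply per-measure Box-Cox transforms (default `TRUE`).
#' @param refit_preprocess refit Box-Cox on the prediction cohort instead of
#'   freezing the exploratory transforms (default `FALSE`).
#' @param threshold classification threshold.
#' @param seed root seed.
#' @return an `experiment1_report` list.
#' @export
run_experiment1 <- function(exploratory, prediction = NULL,
                            families = model_families,
                            scheme = cv_scheme(seed = 1L), impute_k = 5,
                            boxcox = TRUE, refit_preprocess = FALSE,
                            threshold = 0.5, seed = 1L) {
  prep <- function(scores, transforms = NULL) {
    if (boxcox) {
      if (is.null(transforms)) {
        bc <- boxcox_matrix(scores)
        scores <- bc$scores
        transforms <- bc$transforms
      } else {
        # frozen transforms: new-cohort values outside the training support
        # are clipped to the edge of the positive domain before applying
        for (nm in names(transforms)) {
          tr <- transforms[[nm]]
          if (is.null(tr) || !nm %in% colnames(scores)) next
          floor_val <- 1e-6 - tr$shift
          scores[, nm] <- boxcox_apply(pmax(scores[, nm], floor_val), tr)
        }
      }
    }
    if (anyNA(scores)) scores <- knn_impute(scores, k = impute_k)
    list(scores = scores, transforms = transforms)
  }
  expl <- suppressWarnings(prep(exploratory$scores))
  screen <- suppressWarnings(univariate_screen(expl$scores,
                                               exploratory$outcomes))
  cv <- lapply(families, function(fam)
    repeated_cv(expl$scores, exploratory$outcomes,
                model_config(fam, threshold = threshold, seed = seed),
                scheme))
  names(cv) <- families
  ensemble <- fit_ensemble(expl$scores, exploratory$outcomes, families,
                           threshold = threshold, seed = seed)
  report <- list(
    screen = screen,
    cross_validation = cv,
    cv_table = do.call(rbind, lapply(cv, function(r)
      data.frame(family = r$family,
                 accuracy_train = r$resubstitution$accuracy,
                 auc_train = r$resubstitution$auc,
                 accuracy_cv = r$summary$accuracy, auc_cv = r$summary$auc,
                 q1_accuracy_cv = r$summary$q1_accuracy,
                 q4_accuracy_cv = r$summary$q4_accuracy))),
    importance = ensemble$importance,
    ensemble = ensemble,
    manifest = run_manifest(seed, list(
      families = families, folds = scheme$folds, repeats = scheme$repeats,
      stratified = scheme$stratified, impute_k = impute_k, boxcox = boxcox,
      refit_preprocess = refit_preprocess, threshold = threshold)))
  if (!is.null(prediction)) {
    pred_prep <- suppressWarnings(
      if (refit_preprocess) prep(prediction$scores)
      else prep(prediction$scores, transforms = expl$transforms))
    probs <- predict_ensemble(ensemble, pred_prep$scores)
    truth <- as.character(outcome_factor(prediction$outcomes))
    metrics <- do.call(rbind, lapply(families, function(fam) {
      p <- probs[, fam]
      qa <- tryCatch(quartile_accuracy(p, truth, threshold),
                     error = function(e) list(q4_accuracy = NA_real_))
      data.frame(family = fam, auc = auc_roc(p, truth),
                 accuracy = mean(classify_threshold(p, threshold) == truth),
                 upper_quartile_accuracy = qa$q4_accuracy)
    }))
    ttests <- do.call(rbind, lapply(families, function(fam) {
      all_t <- group_probability_ttest(probs[, fam], truth, "all")
      q_t <- tryCatch(group_probability_ttest(probs[, fam], truth, "q1_and_q4"),
                      error = function(e) list(t = NA, df = NA, p = NA))
      data.frame(family = fam, t_all = all_t$t, df_all = all_t$df,
                 p_all = all_t$p, t_q1q4 = q_t$t, df_q1q4 = q_t$df,
                 p_q1q4 = q_t$p)
    }))
    report$prediction <- list(probabilities = probs, metrics = metrics,
                              ttests = ttests)
  }
  structure(report, class = "experiment1_report")
}

#' Consensus-screen and replication workflow
#'
#' Exploratory stage: runs the cognition x performance association grid,
#' aggregates directional counts per cognitive measure, tests the aggregates
#' against the sign-randomness null, and selects a short battery. Replication
#' stage (optional): computes standardized-beta panels for the selected
#' measures on an independent cohort and runs one-tailed one-sample tests in
#' the directions carried over from the exploratory screen.
#'
#' @param cognition dogs x cognitive-measures matrix (exploratory cohort).
#' @param performance `performance_table` or orientation-normalized matrix.
#' @param n_categories per-measure category counts for discretization
#'   (see [association_grid()]).
#' @param alpha per-test significance level (default 0.05, uncorrected).
#' @param selection_threshold minimum `|aggregate|` for battery selection.
#' @param manual_includes measures to force into the battery.
#' @param replication optional list with `cognition` and `performance` for an
#'   independent cohort.
#' @param directions optional named direction vector for the replication
#'   stage; defaults to the sign of the exploratory aggregates of the
#'   selected measures (measures with aggregate 0 need an explicit entry).
#' @param seed root seed recorded in the manifest.
#' @return an `experiment2_report` list.
#' @export
run_experiment2 <- function(cognition, performance, n_categories = 2,
                            alpha = 0.05, selection_threshold = 3,
                            manual_includes = character(0),
                            replication = NULL, directions = NULL,
                            seed = 1L) {
  grid <- association_grid(cognition, performance, n_categories, alpha)
  aggregates <- build_aggregate_table(grid)
  consensus <- consensus_null_test(aggregates)
  battery <- select_short_battery(aggregates, selection_threshold,
                                  manual_includes)
  report <- list(associations = grid, aggregates = aggregates,
                 consensus = consensus, battery = battery,
                 manifest = run_manifest(seed, list(
                   n_categories = n_categories, alpha = alpha,
                   selection_threshold = selection_threshold,
                   manual_includes = manual_includes)))
  if (!is.null(replication)) {
    if (is.null(directions)) {
      if (any(battery$aggregate == 0))
        stop("replication needs an explicit direction for measure(s) with ",
             "aggregate 0: ",
             paste(battery$cognitive_measure[battery$aggregate == 0],
                   collapse = ", "))
      directions <- stats::setNames(
        ifelse(battery$aggregate > 0, "positive", "negative"),
        battery$cognitive_measure)
    }
    report$directions <- directions
    report$replication <- replication_test(replication$cognition,
                                           replication$performance,
                                           directions)
  }
  structure(report, class = "experiment2_report")
}

#' Bundled exploratory detection-dog association counts
#'
#' The per-measure counts of significant positive, negative, and neutral
#' associations from an exploratory detection-dog consensus screen of the
#' full test battery against a panel of performance measures, as published in
#' tabulated (count) form. Useful as a worked example for
#' [aggregate_from_counts()], [consensus_null_test()] and
#' [select_short_battery()].
#'
#' @return data.frame with columns `measure`, `total`, `negative`, `neutral`,
#'   `positive`.
#' @export
detection_screen_counts <- function() {
  path <- system.file("extdata", "detection_screen_counts.tsv",
                      package = "caninecog")
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE, quote = "", comment.char = "")
}
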