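# Cohort rosters, cognitive score matrices, and exclusion accounting.

#' Measure vocabulary of the Dog Cognition Test Battery
#'
#' The 25-task battery yields one or more numeric scores per dog per task;
#' several tasks contribute sub-measures written as a parenthetical suffix,
#' e.g. `"unsolvable task (look at experimenter)"` or
#' `"causal reasoning (visual)"`. Measure-name matching throughout the package
#' is case-insensitive and whitespace/dash-normalized.
#'
#' @return Character vector of base task names (normalized form).
#' @export
dctb_measures <- function() {
  c("affect discrimination", "arm pointing", "causal reasoning",
    "contagious yawning", "cylinder", "detour navigation", "gaze direction",
    "hiding-finding", "inferential reasoning", "laterality: first step",
    "laterality: object manipulation", "marker cue", "memory-distraction",
    "odor control trials", "odor discrimination", "perspective-taking",
    "reaching", "retrieval", "reward preference", "rotation", "sensory bias",
    "social referencing", "spatial perseveration", "spatial transpositions",
    "transparent obstacle", "unsolvable task", "visual discrimination",
    "working memory")
}

#' Normalize a measure name
#'
#' Lower-cases, converts unicode dashes to `-`, collapses whitespace, and
#' removes spaces around hyphens and before colons, so that
#' `"Memory — Distraction"` and `"memory-distraction"` compare equal.
#'
#' @param x character vector of measure names.
#' @return normalized character vector.
#' @export
normalize_measure_name <- function(x) {
  x <- tolower(x)
  x <- gsub("[–—−]", "-", x)
  x <- gsub("\\s+", " ", trimws(x))
  x <- gsub(" ?- ?", "-", x)
  x <- gsub(" ?: ?", ": ", x)
  x
}

# strip a parenthetical sub-measure suffix: "causal reasoning (visual)" ->
# "causal reasoning"
measure_base <- function(x) {
  trimws(sub("\\s*\\([^)]*\\)\\s*$", "", x))
}

#' Check measure names against the controlled vocabulary
#'
#' @param names character vector of (possibly suffixed) measure names.
#' @param vocabulary character vector of base names; defaults to
#'   [dctb_measures()].
#' @return normalized names, invisibly; errors on any unknown base name.
#' @export
check_measure_names <- function(names, vocabulary = dctb_measures()) {
  norm <- normalize_measure_name(names)
  base <- measure_base(norm)
  bad <- setdiff(unique(base), normalize_measure_name(vocabulary))
  if (length(bad) > 0) {
    stop("unknown cognitive measure name(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  invisible(norm)
}

valid_status_flags <- c("hearing_transfer", "medical_release", "other_program",
                        "in_training", "behavioral_release", "serviceable",
                        "unserviceable_behavioral")

#' Load a cohort roster and cognitive score matrix
#'
#' Reads two delimited files: a dog roster (columns `dog_id`, `sex`, `breed`,
#' `age_years`, `cohort`, `status_flags` — semicolon-separated —, optional
#' `outcome` and `aborted_tasks`) and a scores file (`dog_id` plus one column
#' per cognitive measure). Rows of the returned matrix follow roster order.
#' Empty cells and `"NA"` are read as missing.
#'
#' @param roster_path,scores_path paths to delimited text files.
#' @param delim field delimiter (default `","`).
#' @param vocabulary controlled vocabulary for measure names; `NULL` disables
#'   the check.
#' @return list with elements `roster` (data.frame, one row per dog) and
#'   `scores` (numeric matrix, dogs x measures, `NA` = missing, rownames =
#'   dog ids).
#' @export
load_cohort <- function(roster_path, scores_path, delim = ",",
                        vocabulary = dctb_measures()) {
  roster <- utils::read.table(roster_path, header = TRUE, sep = delim,
                              stringsAsFactors = FALSE, check.names = FALSE,
                              na.strings = c("", "NA"), quote = "\"",
                              comment.char = "")
  req <- c("dog_id", "sex", "breed", "age_years", "cohort", "status_flags")
  miss <- setdiff(req, names(roster))
  if (length(miss) > 0)
    stop("roster is missing required column(s): ", paste(miss, collapse = ", "))
  roster$dog_id <- as.character(roster$dog_id)
  dup <- roster$dog_id[duplicated(roster$dog_id)]
  if (length(dup) > 0)
    stop("duplicate dog_id in roster: ", paste(unique(dup), collapse = ", "))
  if (any(!is.na(roster$age_years) & roster$age_years <= 0))
    stop("age_years must be positive")
  roster$status_flags <- as.character(roster$status_flags)
  roster$status_flags[is.na(roster$status_flags)] <- ""
  flag_list <- strsplit(roster$status_flags, ";", fixed = TRUE)
  bad <- setdiff(unique(trimws(unlist(flag_list))),
                 c(valid_status_flags, ""))
  if (length(bad) > 0)
    stop("unknown status flag(s): ", paste(bad, collapse = ", "))
  if (!"outcome" %in% names(roster)) roster$outcome <- NA_character_
  known_out <- is.na(roster$outcome) | roster$outcome %in% c("graduate", "release")
  if (!all(known_out))
    stop("outcome must be 'graduate', 'release', or missing")

  raw <- utils::read.table(scores_path, header = TRUE, sep = delim,
                           stringsAsFactors = FALSE, check.names = FALSE,
                           colClasses = "character", quote = "\"",
                           comment.char = "")
  if (!"dog_id" %in% names(raw)) stop("scores file is missing 'dog_id'")
  sid <- raw$dog_id
  if (anyDuplicated(sid))
    stop("duplicate dog_id in scores file: ",
         paste(unique(sid[duplicated(sid)]), collapse = ", "))
  if (!setequal(sid, roster$dog_id))
    stop("scores file dog_ids do not match roster dog_ids")
  meas_cols <- setdiff(names(raw), "dog_id")
  norm_names <- normalize_measure_name(meas_cols)
  if (anyDuplicated(norm_names))
    stop("duplicate measure names after normalization")
  if (!is.null(vocabulary)) check_measure_names(meas_cols, vocabulary)

  mat <- matrix(NA_real_, nrow = nrow(roster), ncol = length(meas_cols),
                dimnames = list(roster$dog_id, norm_names))
  for (j in seq_along(meas_cols)) {
    cell <- raw[[meas_cols[j]]]
    missing <- is.na(cell) | trimws(cell) == "" | trimws(cell) == "NA"
    val <- suppressWarnings(as.numeric(cell))
    bad <- which(!missing & is.na(val))
    if (length(bad) > 0)
      stop(sprintf("non-numeric score '%s' for dog '%s', measure '%s'",
                   cell[bad[1]], sid[bad[1]], meas_cols[j]))
    val[missing] <- NA_real_
    mat[sid, j] <- val
  }
  list(roster = roster, scores = mat)
}

#' Write a cohort back to delimited files
#'
#' Inverse of [load_cohort()]: missing score cells are written as empty
#' strings, so a write/read round trip preserves values, missingness and
#' ordering.
#'
#' @param cohort list with `roster` and `scores` as returned by [load_cohort()].
#' @param roster_path,scores_path output paths.
#' @param delim field delimiter.
#' @return invisibly, the two paths.
#' @export
write_cohort <- function(cohort, roster_path, scores_path, delim = ",") {
  utils::write.table(cohort$roster, roster_path, sep = delim, na = "",
                     row.names = FALSE, quote = FALSE)
  df <- data.frame(dog_id = rownames(cohort$scores), cohort$scores,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, scores_path, sep = delim, na = "",
                     row.names = FALSE, quote = FALSE)
  invisible(c(roster_path, scores_path))
}

#' Define a cohort exclusion rule
#'
#' Three kinds of rule are supported, mirroring how working-dog studies
#' assemble their analytic samples: removal by program status flag (e.g.
#' transfer to a different program, medical release), removal of dogs that
#' aborted more than a permitted number of battery tasks, and removal of dogs
#' missing more than a permitted number of cognitive predictor measures.
#'
#' @param name label used in the exclusion report.
#' @param kind one of `"status_flag"`, `"max_aborted_tasks"`,
#'   `"max_missing_predictors"`.
#' @param parameter for `status_flag`, a character vector of flags; for the
#'   other kinds, a single non-negative integer (dogs exceeding it are
#'   removed).
#' @return an `exclusion_rule` object.
#' @export
exclusion_rule <- function(name, kind, parameter) {
  kind <- match.arg(kind, c("status_flag", "max_aborted_tasks",
                            "max_missing_predictors"))
  if (kind == "status_flag") {
    bad <- setdiff(parameter, valid_status_flags)
    if (length(bad) > 0)
      stop("unknown status flag(s) in rule '", name, "': ",
           paste(bad, collapse = ", "))
  } else {
    if (!is.numeric(parameter) || length(parameter) != 1 || parameter < 0)
      stop("parameter for '", kind, "' must be a single non-negative integer")
    parameter <- as.integer(parameter)
  }
  structure(list(name = name, kind = kind, parameter = parameter),
            class = "exclusion_rule")
}

rule_matches <- function(rule, roster, scores) {
  switch(rule$kind,
    status_flag = {
      flags <- strsplit(roster$status_flags, ";", fixed = TRUE)
      vapply(flags, function(f) any(trimws(f) %in% rule$parameter), logical(1))
    },
    max_aborted_tasks = {
      if (!"aborted_tasks" %in% names(roster))
        stop("rule '", rule$name,
             "' needs an 'aborted_tasks' column in the roster")
      ab <- roster$aborted_tasks
      ab[is.na(ab)] <- 0
      ab > rule$parameter
    },
    max_missing_predictors = {
      rowSums(is.na(scores)) > rule$parameter
    })
}

#' Apply exclusion rules to a cohort
#'
#' Rules are applied in the listed order and each dog is removed by at most
#' one rule (the first that matches), so the report's counts always reconcile:
#' `initial_n = final_n + sum(removed)`.
#'
#' @param roster roster data.frame (see [load_cohort()]).
#' @param scores dogs x measures numeric matrix aligned with the roster.
#' @param rules list of [exclusion_rule()] objects.
#' @return list with `roster`, `scores` (both filtered) and `report`, an
#'   `exclusion_report` with fields `initial_n`, `removed` (named integer
#'   vector) and `final_n`.
#' @export
apply_exclusions <- function(roster, scores, rules) {
  stopifnot(nrow(roster) == nrow(scores))
  removed_by <- rep(NA_character_, nrow(roster))
  for (rule in rules) {
    hit <- rule_matches(rule, roster, scores) & is.na(removed_by)
    removed_by[hit] <- rule$name
  }
  counts <- vapply(rules, function(r) sum(removed_by == r$name, na.rm = TRUE),
                   integer(1))
  names(counts) <- vapply(rules, `[[`, character(1), "name")
  keep <- is.na(removed_by)
  report <- structure(
    list(initial_n = nrow(roster), removed = counts, final_n = sum(keep)),
    class = "exclusion_report")
  stopifnot(report$final_n == report$initial_n - sum(report$removed))
  list(roster = roster[keep, , drop = FALSE],
       scores = scores[keep, , drop = FALSE],
       report = report)
}

#' @export
print.exclusion_report <- function(x, ...) {
  cat("Cohort exclusion report\n")
  cat("  initial n:", x$initial_n, "\n")
  for (nm in names(x$removed))
    cat(sprintf("  - %s: removed %d\n", nm, x$removed[[nm]]))
  cat("  final n:  ", x$final_n, "\n")
  invisible(x)
}

#' Per-dog and per-measure missingness counts
#'
#' @param scores dogs x measures matrix with `NA` for missing cells.
#' @return list with `per_dog` and `per_measure` named integer vectors; both
#'   sum to the total number of missing cells.
#' @export
missingness_summary <- function(scores) {
  miss <- is.na(scores)
  list(per_dog = rowSums(miss), per_measure = colSums(miss),
       total = sum(miss))
}
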