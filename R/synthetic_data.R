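# Synthetic cohorts with the statistical structure the analyses assume:
# latent-factor cognitive scores, logit-model graduation outcomes with a
# calibrated base rate, training logs and ordinal rating series driven by a
# latent quality score, and independent missingness.
#
# All randomness flows from one root seed through named substreams, so each
# generator stage is independently reproducible.

substream_seed <- function(seed, name) {
  h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name)))
  as.integer((as.numeric(seed) * 7919 + h * 104729) %% .Machine$integer.max)
}

#' Configure a synthetic working-dog cohort
#'
#' Defaults emulate the cohorts of applied screening programs: about a
#' hundred dogs, eleven battery measures loading on three latent cognitive
#' factors, a graduation base rate of 68%, and (for the detection-dog arm)
#' training logs averaging 33 weeks per dog.
#'
#' @param n_dogs number of dogs (default 111).
#' @param measure_names cognitive measure names (default: an 11-measure
#'   short battery drawn from [dctb_measures()]).
#' @param n_factors number of latent cognitive factors (default 3).
#' @param loadings measures x factors loading matrix; default assigns each
#'   measure a loading of 0.7 on one factor, round-robin.
#' @param noise_sd unique (non-shared) noise SD per measure (default 0.7).
#' @param outcome_coefficients named standardized log-odds coefficients of
#'   the graduation model (default: all zero — a null cohort).
#' @param target_base_rate expected graduation rate (default 0.68).
#' @param planted_effects named correlations between cognitive measures and
#'   the latent detection-quality score (default none).
#' @param missingness_rate probability each observed cell is masked
#'   (default 0).
#' @param n_weeks_mean mean training-log weeks per dog (default 33).
#' @param seed root seed for all substreams.
#' @return a `synthetic_config` list.
#' @export
synthetic_config <- function(n_dogs = 111,
                             measure_names = c(
                               "causal reasoning (visual)",
                               "spatial transpositions",
                               "inferential reasoning", "cylinder",
                               "social referencing", "unsolvable task",
                               "odor discrimination",
                               "laterality: object manipulation",
                               "laterality: first step", "arm pointing",
                               "reward preference"),
                             n_factors = 3, loadings = NULL, noise_sd = 0.7,
                             outcome_coefficients = NULL,
                             target_base_rate = 0.68,
                             planted_effects = NULL,
                             missingness_rate = 0, n_weeks_mean = 33,
                             seed = 1L) {
  measure_names <- normalize_measure_name(measure_names)
  p <- length(measure_names)
  if (is.null(loadings)) {
    loadings <- matrix(0, p, n_factors,
                       dimnames = list(measure_names, NULL))
    loadings[cbind(seq_len(p), rep_len(seq_len(n_factors), p))] <- 0.7
  }
  if (target_base_rate <= 0 || target_base_rate >= 1)
    stop("target_base_rate must be in (0, 1)")
  if (missingness_rate < 0 || missingness_rate >= 1)
    stop("missingness_rate must be in [0, 1)")
  structure(list(n_dogs = n_dogs, measure_names = measure_names,
                 n_factors = n_factors, loadings = loadings,
                 noise_sd = noise_sd,
                 outcome_coefficients = outcome_coefficients,
                 target_base_rate = target_base_rate,
                 planted_effects = planted_effects,
                 missingness_rate = missingness_rate,
                 n_weeks_mean = n_weeks_mean, seed = as.integer(seed)),
            class = "synthetic_config")
}

#' Generate a cognitive score matrix from a latent factor model
#'
#' `scores = loadings %*% factors + unique noise`; empirical inter-measure
#' correlations converge to the loading-implied values as the cohort grows.
#'
#' @param config a [synthetic_config()].
#' @return list with `scores` (dogs x measures matrix, rownames `dog_001`,
#'   ...) and `factors` (dogs x factors matrix of latent scores).
#' @export
gen_cognitive_matrix <- function(config) {
  if (all(config$loadings == 0) && config$noise_sd == 0)
    stop("degenerate configuration: zero loadings and zero noise")
  set.seed(substream_seed(config$seed, "cognitive"))
  n <- config$n_dogs
  factors <- matrix(stats::rnorm(n * config$n_factors), n, config$n_factors)
  noise <- matrix(stats::rnorm(n * nrow(config$loadings), sd = config$noise_sd),
                  n, nrow(config$loadings))
  scores <- factors %*% t(config$loadings) + noise
  dimnames(scores) <- list(sprintf("dog_%03d", seq_len(n)),
                           rownames(config$loadings))
  list(scores = scores, factors = factors)
}

#' Draw graduation outcomes from a calibrated logit model
#'
#' The linear predictor is the named coefficient vector applied to z-scored
#' measures; the intercept is auto-calibrated (by root finding) so the
#' expected graduation rate matches the target within 0.01.
#'
#' @param scores dogs x measures matrix (complete).
#' @param coefficients named standardized log-odds coefficients (`NULL` or
#'   empty = pure-noise outcome).
#' @param target_base_rate expected graduation rate in (0, 1).
#' @param seed integer seed.
#' @return list with `outcome` (`"graduate"`/`"release"` per dog),
#'   `probability` (true success probabilities), `intercept`.
#' @export
gen_graduation_outcomes <- function(scores, coefficients = NULL,
                                    target_base_rate = 0.68, seed = 1L) {
  n <- nrow(scores)
  eta <- numeric(n)
  if (!is.null(coefficients) && length(coefficients) > 0) {
    unknown <- setdiff(names(coefficients), colnames(scores))
    if (length(unknown) > 0)
      stop("coefficients reference unknown measure(s): ",
           paste(unknown, collapse = ", "))
    z <- apply(scores[, names(coefficients), drop = FALSE], 2, zscore)
    eta <- drop(z %*% coefficients)
  }
  f <- function(b0) mean(stats::plogis(b0 + eta)) - target_base_rate
  b0 <- stats::uniroot(f, c(-50, 50), tol = 1e-10)$root
  prob <- stats::plogis(b0 + eta)
  if (abs(mean(prob) - target_base_rate) > 0.01)
    stop("target base rate unreachable with the given coefficients")
  set.seed(substream_seed(seed, "outcomes"))
  outcome <- ifelse(stats::runif(n) < prob, "graduate", "release")
  list(outcome = stats::setNames(outcome, rownames(scores)),
       probability = prob, intercept = b0)
}

#' Latent detection-quality scores
#'
#' One scalar quality per dog (standard normal), the ground truth that the
#' detection-dog performance records are generated from.
#'
#' @param n_dogs number of dogs.
#' @param seed integer seed.
#' @return named numeric vector.
#' @export
gen_latent_quality <- function(n_dogs, seed = 1L) {
  set.seed(substream_seed(seed, "quality"))
  stats::setNames(stats::rnorm(n_dogs), sprintf("dog_%03d", seq_len(n_dogs)))
}

#' Plant correlations between cognitive measures and latent quality
#'
#' Rebuilds each named measure as
#' `rho * quality + sqrt(1 - rho^2) * independent noise` (both standard
#' normal scale), so its population correlation with quality is `rho`.
#'
#' @param scores dogs x measures matrix.
#' @param quality latent quality vector aligned with rows.
#' @param effects named vector of target correlations in (-1, 1).
#' @param seed integer seed.
#' @return modified scores matrix.
#' @export
plant_quality_effects <- function(scores, quality, effects, seed = 1L) {
  if (is.null(effects) || length(effects) == 0) return(scores)
  unknown <- setdiff(names(effects), colnames(scores))
  if (length(unknown) > 0)
    stop("planted effects reference unknown measure(s): ",
         paste(unknown, collapse = ", "))
  set.seed(substream_seed(seed, "planted"))
  zq <- zscore(quality)
  for (m in names(effects)) {
    rho <- effects[[m]]
    stopifnot(abs(rho) < 1)
    scores[, m] <- rho * zq + sqrt(1 - rho^2) * stats::rnorm(nrow(scores))
  }
  scores
}

#' Generate weekly training-log records
#'
#' Per dog, a number of weeks drawn around `n_weeks_mean` (Poisson, at least
#' 1); per week, 1-5 reported training days (so some weeks fall below the
#' 3-day scoring eligibility) and a 0-3 prevalence score per behavioural
#' category from an ordered-logit model whose severity decreases with latent
#' quality.
#'
#' @param quality named latent quality vector (one per dog).
#' @param n_weeks_mean mean weeks per dog (default 33).
#' @param severity effect of quality on deficiency severity (default 1).
#' @param seed integer seed.
#' @return data.frame in the [score_training_logs()] input layout.
#' @export
gen_training_logs <- function(quality, n_weeks_mean = 33, severity = 1,
                              seed = 1L) {
  set.seed(substream_seed(seed, "logs"))
  cats <- log_categories()
  thresholds <- c(1, 2.5, 4)  # latent cutpoints for prevalence 1/2/3
  rows <- list()
  for (i in seq_along(quality)) {
    n_weeks <- max(1L, stats::rpois(1, n_weeks_mean))
    days <- sample(1:5, n_weeks, replace = TRUE)
    for (w in seq_len(n_weeks)) {
      latent <- -severity * quality[i] +
        stats::rlogis(length(cats), scale = 0.8)
      sc <- vapply(latent, function(l) sum(l > thresholds), numeric(1))
      row <- data.frame(dog_id = names(quality)[i], week_index = w,
                        days_reported = days[w], stringsAsFactors = FALSE)
      row[cats] <- as.list(sc)
      rows[[length(rows) + 1]] <- row
    }
  }
  do.call(rbind, rows)
}

#' Generate an ordinal weekly rating series per dog
#'
#' Ratings are drawn from an ordered logit on latent quality: the better the
#' dog, the more records rated good or excellent.
#'
#' @param quality named latent quality vector.
#' @param n_records_mean mean records per dog (default 97).
#' @param seed integer seed.
#' @return data.frame with `dog_id`, `record_index`, `rating`.
#' @export
gen_ordinal_series <- function(quality, n_records_mean = 97, seed = 1L) {
  set.seed(substream_seed(seed, "ordinal"))
  levs <- c("poor", "fair", "good", "excellent")
  thresholds <- c(-2, -0.5, 1)
  rows <- list()
  for (i in seq_along(quality)) {
    n_rec <- max(1L, stats::rpois(1, n_records_mean))
    latent <- quality[i] + stats::rlogis(n_rec)
    idx <- vapply(latent, function(l) 1 + sum(l > thresholds), numeric(1))
    rows[[length(rows) + 1]] <- data.frame(
      dog_id = names(quality)[i], record_index = seq_len(n_rec),
      rating = levs[idx], stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Mask observed cells at random
#'
#' Each observed cell is independently set missing with probability `rate`;
#' already-missing cells are never unmasked.
#'
#' @param scores dogs x measures matrix.
#' @param rate missingness probability in \[0, 1).
#' @param seed integer seed.
#' @return matrix with additional `NA` cells.
#' @export
inject_missingness <- function(scores, rate, seed = 1L) {
  if (rate < 0 || rate >= 1) stop("rate must be in [0, 1)")
  if (rate == 0) return(scores)
  set.seed(substream_seed(seed, "missingness"))
  mask <- matrix(stats::runif(length(scores)) < rate, nrow(scores))
  scores[mask] <- NA_real_
  scores
}

#' Simulate a complete synthetic cohort
#'
#' Ties the stage generators together: cognitive matrix (with optional
#' planted quality effects and missingness), roster with graduation
#' outcomes, latent quality, training logs and ordinal rating series.
#'
#' @param config a [synthetic_config()].
#' @param detection also generate training logs and ordinal series (default
#'   `TRUE`).
#' @return list with `roster`, `scores`, `factors`, `quality`,
#'   `true_probability`, and (if `detection`) `training_logs`,
#'   `ordinal_series`.
#' @export
simulate_cohort <- function(config, detection = TRUE) {
  cm <- gen_cognitive_matrix(config)
  quality <- gen_latent_quality(config$n_dogs, config$seed)
  scores <- plant_quality_effects(cm$scores, quality,
                                  config$planted_effects, config$seed)
  out <- gen_graduation_outcomes(scores, config$outcome_coefficients,
                                 config$target_base_rate, config$seed)
  scores_obs <- inject_missingness(scores, config$missingness_rate,
                                   config$seed)
  set.seed(substream_seed(config$seed, "roster"))
  n <- config$n_dogs
  roster <- data.frame(
    dog_id = rownames(scores),
    sex = sample(c("female", "male"), n, replace = TRUE, prob = c(0.65, 0.35)),
    breed = sample(c("labrador retriever", "golden retriever",
                     "labrador x golden cross"), n, replace = TRUE,
                   prob = c(0.12, 0.02, 0.86)),
    age_years = round(stats::rnorm(n, 2.0, 0.2), 2),
    cohort = "exploratory",
    status_flags = "",
    outcome = unname(out$outcome),
    stringsAsFactors = FALSE)
  res <- list(roster = roster, scores = scores_obs, factors = cm$factors,
              quality = quality, true_probability = out$probability)
  if (detection) {
    res$training_logs <- gen_training_logs(quality, config$n_weeks_mean,
                                           seed = config$seed)
    res$ordinal_series <- gen_ordinal_series(quality, seed = config$seed)
  }
  res
}
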