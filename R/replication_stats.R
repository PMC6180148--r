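# Replication analysis: standardized-coefficient panels with one-tailed
# one-sample tests, and the inter-rater reliability statistics.

#' Standardized regression coefficient between two variables
#'
#' Slope of the least-squares fit of z-scored `y` on z-scored `x`, computed
#' on pairwise-complete observations. For a single predictor this equals the
#' Pearson correlation.
#'
#' @param x predictor (cognitive measure) values.
#' @param y outcome (performance measure) values.
#' @return list with `beta` and `n_used`.
#' @export
standardized_beta <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  if (sum(ok) < 3) stop("need at least 3 pairwise-complete observations")
  if (stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0)
    stop("zero variance in x or y")
  zx <- zscore(x[ok]); zy <- zscore(y[ok])
  list(beta = unname(stats::coef(stats::lm(zy ~ zx))[2]), n_used = sum(ok))
}

#' Compute a panel of standardized betas for one predictor
#'
#' One `standardized_beta()` per performance measure, each on its own
#' pairwise-complete sample (data availability typically varies across
#' measures).
#'
#' @param x predictor values, one per dog (named by dog id or aligned with
#'   the rows of `performance`).
#' @param performance dogs x measures matrix of orientation-normalized
#'   performance values.
#' @return data.frame with `outcome`, `beta`, `n_used` (one row per usable
#'   measure; measures with < 3 complete pairs are dropped with a warning).
#' @export
beta_panel <- function(x, performance) {
  perf <- if (inherits(performance, "performance_table")) performance$values
          else performance
  rows <- list()
  for (pm in colnames(perf)) {
    b <- tryCatch(standardized_beta(x, perf[, pm]), error = function(e) NULL)
    if (is.null(b)) {
      warning("outcome '", pm, "' dropped from beta panel", call. = FALSE)
      next
    }
    rows[[length(rows) + 1]] <- data.frame(outcome = pm, beta = b$beta,
                                           n_used = b$n_used,
                                           stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' One-tailed one-sample test on a panel of betas
#'
#' Tests the null that the betas for one predictor have mean 0 against the
#' one-sided alternative in the hypothesized direction (carried over from an
#' earlier exploratory screen). `t = mean/SEM` with `df = n - 1`; the
#' one-tailed p exceeds 0.5 when the observed mean opposes the hypothesis,
#' and the two opposite-direction one-tailed p-values always sum to 1.
#'
#' @param betas numeric vector of standardized coefficients (>= 2).
#' @param direction `"positive"` or `"negative"` hypothesized association.
#' @return list with `mean_beta`, `sem_beta`, `t`, `df`, `p_one_tailed`,
#'   `hypothesized_direction`.
#' @export
beta_panel_test <- function(betas, direction = c("positive", "negative")) {
  direction <- match.arg(direction)
  if (length(betas) < 2) stop("need at least 2 betas")
  sem <- stats::sd(betas) / sqrt(length(betas))
  if (sem == 0) stop("zero standard error among betas")
  t <- mean(betas) / sem
  df <- length(betas) - 1
  p <- if (direction == "positive") stats::pt(t, df, lower.tail = FALSE)
       else stats::pt(t, df)
  list(mean_beta = mean(betas), sem_beta = sem, t = t, df = df,
       p_one_tailed = p, hypothesized_direction = direction)
}

#' Cohen's kappa for two raters
#'
#' Chance-corrected agreement `(p_obs - p_chance) / (1 - p_chance)` with
#' chance agreement from the marginal products. If both raters are constant
#' and identical (chance agreement 1), kappa is defined as 1 by convention,
#' with a message.
#'
#' @param ratings_a,ratings_b equal-length categorical vectors.
#' @return list with `kappa`, `p_obs`, `p_chance`, `n_items`.
#' @export
cohen_kappa <- function(ratings_a, ratings_b) {
  if (length(ratings_a) != length(ratings_b)) stop("length mismatch")
  n <- length(ratings_a)
  if (n < 2) stop("need at least 2 rated items")
  levs <- sort(unique(c(as.character(ratings_a), as.character(ratings_b))))
  a <- factor(ratings_a, levels = levs)
  b <- factor(ratings_b, levels = levs)
  tab <- table(a, b) / n
  p_obs <- sum(diag(tab))
  p_chance <- sum(rowSums(tab) * colSums(tab))
  kappa <- if (p_chance >= 1) {
    message("both raters constant and identical; kappa defined as 1 by convention")
    1
  } else (p_obs - p_chance) / (1 - p_chance)
  list(kappa = kappa, p_obs = p_obs, p_chance = p_chance, n_items = n)
}

#' Pearson correlation between two raters' continuous scores
#'
#' @param x,y numeric vectors (pairwise-complete n >= 3, non-constant).
#' @return list with `r` and `n_items`.
#' @export
pearson_r <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  if (sum(ok) < 3) stop("need at least 3 pairwise-complete observations")
  if (stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) stop("zero variance")
  list(r = stats::cor(x[ok], y[ok]), n_items = sum(ok))
}

#' Replication test for a set of predictors
#'
#' Runs [beta_panel()] + [beta_panel_test()] for each predictor in a
#' direction manifest (typically the short-battery selection of an earlier
#' exploratory screen with its observed association directions).
#'
#' @param cognition dogs x cognitive-measures matrix.
#' @param performance dogs x performance-measures matrix
#'   (orientation-normalized) or a `performance_table`.
#' @param directions named character vector, `"positive"`/`"negative"` per
#'   predictor.
#' @return data.frame with one row per predictor: `predictor`, `direction`,
#'   `mean_beta`, `sem_beta`, `t`, `df`, `p_one_tailed`, `n_outcomes`.
#' @export
replication_test <- function(cognition, performance, directions) {
  unknown <- setdiff(names(directions), colnames(cognition))
  if (length(unknown) > 0)
    stop("direction manifest names unknown predictor(s): ",
         paste(unknown, collapse = ", "))
  perf <- if (inherits(performance, "performance_table")) performance$values
          else performance
  dogs <- intersect(rownames(cognition), rownames(perf))
  rows <- list()
  for (pred in names(directions)) {
    panel <- beta_panel(cognition[dogs, pred], perf[dogs, , drop = FALSE])
    res <- beta_panel_test(panel$beta, directions[[pred]])
    rows[[length(rows) + 1]] <- data.frame(
      predictor = pred, direction = directions[[pred]],
      mean_beta = res$mean_beta, sem_beta = res$sem_beta, t = res$t,
      df = res$df, p_one_tailed = res$p_one_tailed,
      n_outcomes = nrow(panel), stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
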