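# Predictor preprocessing: Box-Cox, kNN imputation, z-scores, quantile bins.

#' Fit a Box-Cox power transform by profile maximum likelihood
#'
#' Estimates the exponent lambda maximizing the Box-Cox profile
#' log-likelihood on the (shifted) observed values, with a continuous search
#' rather than a fixed grid. Scores that can be zero or negative (several
#' battery measures are counts or proportions) are shifted by `1 - min` so
#' every value used in fitting is strictly positive; already-positive inputs
#' get shift 0.
#'
#' @param values numeric vector; `NA`s are ignored during fitting.
#' @param interval search interval for lambda.
#' @return object of class `boxcox_transform` with fields `shift`, `lambda`,
#'   `fitted_on_n`.
#' @export
boxcox_fit <- function(values, interval = c(-5, 5)) {
  obs <- values[is.finite(values)]
  if (length(obs) < 3) stop("need at least 3 finite values to fit Box-Cox")
  if (stats::sd(obs) == 0) stop("constant input: Box-Cox transform undefined")
  shift <- if (min(obs) > 0) 0 else 1 - min(obs)
  y <- obs + shift
  n <- length(y)
  sum_log <- sum(log(y))
  loglik <- function(lambda) {
    z <- if (abs(lambda) < 1e-8) log(y) else (y^lambda - 1) / lambda
    -n / 2 * log(stats::var(z) * (n - 1) / n) + (lambda - 1) * sum_log
  }
  opt <- stats::optimize(loglik, interval = interval, maximum = TRUE)
  structure(list(shift = shift, lambda = opt$maximum, fitted_on_n = n),
            class = "boxcox_transform")
}

#' Apply a fitted Box-Cox transform
#'
#' Uses the log branch when `lambda` is (numerically) zero. The mapping is
#' strictly increasing, and missing values pass through as missing.
#'
#' @param values numeric vector.
#' @param transform a `boxcox_transform` from [boxcox_fit()] (or a list with
#'   `shift` and `lambda`).
#' @return transformed numeric vector.
#' @export
boxcox_apply <- function(values, transform) {
  y <- values + transform$shift
  bad <- which(is.finite(y) & y <= 0)
  if (length(bad) > 0)
    stop(sprintf("value %g is non-positive after shift %g",
                 values[bad[1]], transform$shift))
  lambda <- transform$lambda
  out <- if (abs(lambda) < 1e-8) log(y) else (y^lambda - 1) / lambda
  out[!is.finite(values)] <- values[!is.finite(values)]
  out
}

#' Box-Cox transform every column of a score matrix
#'
#' Columns with fewer than 3 observed values, or (near-)constant columns —
#' including binary measures — are passed through untouched with a warning,
#' since a power transform is undefined or uninformative there.
#'
#' @param scores dogs x measures numeric matrix (`NA` = missing).
#' @return list with `scores` (transformed matrix) and `transforms` (named
#'   list of `boxcox_transform` or `NULL` for passed-through columns).
#' @export
boxcox_matrix <- function(scores) {
  transforms <- vector("list", ncol(scores))
  names(transforms) <- colnames(scores)
  out <- scores
  for (j in seq_len(ncol(scores))) {
    col <- scores[, j]
    obs <- col[is.finite(col)]
    if (length(obs) < 3 || length(unique(obs)) <= 2) {
      warning("measure '", colnames(scores)[j],
              "' is (near-)constant or too sparse; Box-Cox skipped",
              call. = FALSE)
      next
    }
    tr <- boxcox_fit(col)
    out[, j] <- boxcox_apply(col, tr)
    transforms[[j]] <- tr
  }
  list(scores = out, transforms = transforms)
}

#' K-nearest-neighbour imputation of a score matrix
#'
#' Distances between dogs are mean squared differences over the measures
#' observed in both dogs, computed on per-measure standardized values.
#' Each missing cell is filled with the unweighted mean of the `k` nearest
#' dogs among those with that measure observed. Observed cells are never
#' altered and the procedure is deterministic (ties in distance are broken by
#' row order).
#'
#' @param scores dogs x measures numeric matrix (`NA` = missing).
#' @param k number of neighbours (default 5).
#' @return completed numeric matrix.
#' @export
knn_impute <- function(scores, k = 5) {
  n <- nrow(scores)
  if (k < 1 || k >= n) stop("k must satisfy 1 <= k < number of dogs")
  if (!anyNA(scores)) return(scores)
  mu <- colMeans(scores, na.rm = TRUE)
  sg <- apply(scores, 2, stats::sd, na.rm = TRUE)
  sg[!is.finite(sg) | sg == 0] <- 1
  z <- sweep(sweep(scores, 2, mu, "-"), 2, sg, "/")
  obs <- is.finite(scores)
  if (any(colSums(obs) < k))
    stop("every measure must be observed for at least k dogs")
  out <- scores
  need <- which(rowSums(!obs) > 0)
  for (i in need) {
    shared <- obs & matrix(obs[i, ], n, ncol(scores), byrow = TRUE)
    n_shared <- rowSums(shared)
    n_shared[i] <- 0
    if (all(n_shared == 0))
      stop("dog '", rownames(scores)[i],
           "' shares no observed measure with any other dog")
    diff2 <- sweep(z, 2, z[i, ], "-")^2
    diff2[!shared] <- 0
    d <- ifelse(n_shared > 0, rowSums(diff2) / pmax(n_shared, 1), Inf)
    d[i] <- Inf
    for (j in which(!obs[i, ])) {
      cand <- which(obs[, j] & is.finite(d))
      if (length(cand) < k)
        stop("fewer than k usable neighbours for dog '", rownames(scores)[i],
             "', measure '", colnames(scores)[j], "'")
      nn <- cand[order(d[cand])][seq_len(k)]
      out[i, j] <- mean(scores[nn, j])
    }
  }
  out
}

#' Standardize a numeric vector to z-scores
#'
#' Centred and scaled with the sample (n - 1) standard deviation; missing
#' values are preserved.
#'
#' @param values numeric vector with at least 2 finite values.
#' @return z-scored vector (observed mean 0, SD 1).
#' @export
zscore <- function(values) {
  obs <- values[is.finite(values)]
  if (length(obs) < 2) stop("need at least 2 finite values")
  s <- stats::sd(obs)
  if (s == 0) stop("zero variance: z-score undefined")
  (values - mean(obs)) / s
}

#' Discretize a vector into quantile categories
#'
#' Two categories split at the median; three categories split at the 33.3rd
#' and 66.7th percentiles (linear-interpolation sample quantiles). Values
#' tied with a boundary are assigned to the lower category.
#'
#' @param values numeric vector.
#' @param n_categories 2 or 3.
#' @return ordered factor with levels `below` / `above` (n = 2) or
#'   `below` / `average` / `above` (n = 3); `NA` values stay `NA`.
#' @export
discretize_quantiles <- function(values, n_categories = 2) {
  if (!n_categories %in% c(2, 3)) stop("n_categories must be 2 or 3")
  obs <- values[is.finite(values)]
  if (length(unique(obs)) < n_categories)
    stop("fewer distinct values than categories")
  if (n_categories == 2) {
    cuts <- stats::quantile(obs, 0.5, type = 7, names = FALSE)
    lev <- c("below", "above")
  } else {
    cuts <- stats::quantile(obs, c(1, 2) / 3, type = 7, names = FALSE)
    lev <- c("below", "average", "above")
  }
  idx <- findInterval(values, cuts, left.open = TRUE) + 1L
  factor(lev[idx], levels = lev, ordered = TRUE)
}

#' Freeze a fitted preprocessing state to a plain-text config
#'
#' Serializes per-measure Box-Cox records and the imputation setting as
#' `key: value` lines so that a preprocessing state fitted on one cohort can
#' be re-applied, unchanged, to an independent cohort.
#'
#' @param transforms named list from [boxcox_matrix()].
#' @param k imputation neighbour count.
#' @param path output file path.
#' @return invisibly, `path`.
#' @export
write_preprocess_config <- function(transforms, k, path) {
  lines <- c(sprintf("impute_k: %d", as.integer(k)))
  for (nm in names(transforms)) {
    tr <- transforms[[nm]]
    if (is.null(tr)) {
      lines <- c(lines, sprintf("measure: %s | passthrough", nm))
    } else {
      lines <- c(lines, sprintf(
        "measure: %s | shift: %.17g | lambda: %.17g | fitted_on_n: %d",
        nm, tr$shift, tr$lambda, tr$fitted_on_n))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read back a frozen preprocessing config
#'
#' @param path file written by [write_preprocess_config()].
#' @return list with `k` and `transforms` (named list, `NULL` = passthrough).
#' @export
read_preprocess_config <- function(path) {
  lines <- readLines(path)
  k <- as.integer(sub("impute_k: ", "", lines[1]))
  transforms <- list()
  for (ln in lines[-1]) {
    parts <- strsplit(sub("^measure: ", "", ln), " | ", fixed = TRUE)[[1]]
    nm <- parts[1]
    if (identical(parts[2], "passthrough")) {
      transforms[nm] <- list(NULL)
    } else {
      kv <- as.numeric(sub("^[a-z_]+: ", "", parts[2:4]))
      transforms[[nm]] <- structure(
        list(shift = kv[1], lambda = kv[2], fitted_on_n = as.integer(kv[3])),
        class = "boxcox_transform")
    }
  }
  list(k = k, transforms = transforms)
}
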