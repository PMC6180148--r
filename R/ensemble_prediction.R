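# Graduation-outcome prediction: univariate screening, the eight-family
# classifier ensemble, repeated stratified cross-validation, threshold
# classification, quartile-stratified accuracy, importance scaling, and the
# group comparisons on predicted probabilities.

model_families <- c("GLM", "LDA", "RR", "PLS", "NB", "MARS", "KNN", "RF")

outcome_factor <- function(outcomes) {
  if (is.factor(outcomes)) outcomes <- as.character(outcomes)
  if (is.numeric(outcomes) || is.logical(outcomes))
    outcomes <- ifelse(as.numeric(outcomes) > 0, "graduate", "release")
  if (!all(outcomes %in% c("graduate", "release")))
    stop("outcomes must be 'graduate'/'release' (or 1/0)")
  factor(outcomes, levels = c("release", "graduate"))
}

#' Configure one model family of the ensemble
#'
#' The eight families are: generalized linear model (`GLM`), linear
#' discriminant analysis (`LDA`), regularized (ridge) regression (`RR`),
#' partial least squares (`PLS`), naive Bayes (`NB`), multivariate adaptive
#' regression splines (`MARS`), k-nearest neighbours (`KNN`, 7 neighbours by
#' default), and random forest (`RF`).
#'
#' @param family one of `"GLM"`, `"LDA"`, `"RR"`, `"PLS"`, `"NB"`, `"MARS"`,
#'   `"KNN"`, `"RF"`.
#' @param threshold probability threshold for classifying a dog as a
#'   graduate; strictly between 0 and 1 (default 0.5).
#' @param hyperparameters named list overriding family defaults
#'   (`k` for KNN, `lambda` for RR, `ncomp` for PLS, `ntree` for RF,
#'   `max_terms` for MARS).
#' @param seed integer seed used for stochastic fitters.
#' @return a `model_config` object.
#' @export
model_config <- function(family, threshold = 0.5, hyperparameters = list(),
                         seed = 1L) {
  family <- match.arg(family, model_families)
  if (threshold <= 0 || threshold >= 1)
    stop("threshold must be strictly between 0 and 1")
  defaults <- switch(family,
    KNN = list(k = 7), RR = list(lambda = 0.1, alpha = 0),
    PLS = list(ncomp = 2), RF = list(ntree = 500),
    MARS = list(max_terms = 9, n_knots = 7), list())
  hp <- utils::modifyList(defaults, hyperparameters)
  structure(list(family = family, threshold = threshold,
                 hyperparameters = hp, seed = as.integer(seed)),
            class = "model_config")
}

#' Configure a repeated cross-validation scheme
#'
#' @param folds number of folds (>= 2, default 4).
#' @param repeats number of repeats (default 100).
#' @param stratified keep the class ratio per fold within one dog of the
#'   overall ratio (default `TRUE`).
#' @param seed integer RNG seed; identical schemes give identical splits.
#' @return a `cv_scheme` object.
#' @export
cv_scheme <- function(folds = 4, repeats = 100, stratified = TRUE, seed = 1L) {
  if (folds < 2) stop("folds must be >= 2")
  if (repeats < 1) stop("repeats must be >= 1")
  structure(list(folds = as.integer(folds), repeats = as.integer(repeats),
                 stratified = isTRUE(stratified), seed = as.integer(seed)),
            class = "cv_scheme")
}

# ---- family fitters ---------------------------------------------------------

# NIPALS PLS1 regression of the 0/1 outcome on standardized predictors.
fit_pls1 <- function(x, y01, ncomp) {
  mu <- colMeans(x); sg <- apply(x, 2, stats::sd); sg[sg == 0] <- 1
  E <- sweep(sweep(x, 2, mu, "-"), 2, sg, "/")
  ybar <- mean(y01); f <- y01 - ybar
  p <- ncol(E); ncomp <- min(ncomp, p, nrow(x) - 1)
  W <- P <- matrix(0, p, ncomp); q <- numeric(ncomp)
  for (a in seq_len(ncomp)) {
    w <- drop(crossprod(E, f))
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) { ncomp <- a - 1; break }
    w <- w / nw
    t <- drop(E %*% w); tt <- sum(t^2)
    P[, a] <- drop(crossprod(E, t)) / tt
    q[a] <- sum(f * t) / tt
    E <- E - tcrossprod(t, P[, a])
    f <- f - q[a] * t
    W[, a] <- w
  }
  if (ncomp == 0) stop("PLS: no usable component (constant predictors?)")
  W <- W[, seq_len(ncomp), drop = FALSE]
  P <- P[, seq_len(ncomp), drop = FALSE]
  B <- W %*% solve(crossprod(P, W), q[seq_len(ncomp)])
  list(mu = mu, sg = sg, ybar = ybar, B = drop(B), ncomp = ncomp)
}

predict_pls1 <- function(fit, x) {
  z <- sweep(sweep(x, 2, fit$mu, "-"), 2, fit$sg, "/")
  pmin(pmax(drop(z %*% fit$B) + fit$ybar, 0), 1)
}

# Forward-stagewise adaptive regression splines: hinge-pair basis selected by
# binomial deviance reduction, refit as one logistic model.
fit_mars_logit <- function(x, y01, max_terms = 9, n_knots = 7) {
  n <- nrow(x); p <- ncol(x)
  basis <- matrix(1, n, 1)
  terms <- list()
  var_gain <- stats::setNames(numeric(p), colnames(x))
  dev_fit <- function(B) {
    fit <- suppressWarnings(stats::glm.fit(B, y01, family = stats::binomial()))
    fit$deviance
  }
  cur_dev <- dev_fit(basis)
  knots <- lapply(seq_len(p), function(j) {
    u <- unique(x[, j])
    if (length(u) <= 2) return(numeric(0))
    stats::quantile(u, seq_len(n_knots) / (n_knots + 1), type = 7,
                    names = FALSE)
  })
  while (ncol(basis) + 2 <= max_terms) {
    best <- NULL
    for (j in seq_len(p)) {
      for (t in knots[[j]]) {
        h <- cbind(pmax(x[, j] - t, 0), pmax(t - x[, j], 0))
        d <- tryCatch(dev_fit(cbind(basis, h)), error = function(e) Inf)
        if (is.null(best) || d < best$dev) best <- list(dev = d, j = j, t = t, h = h)
      }
    }
    if (is.null(best) || cur_dev - best$dev < 1e-4) break
    var_gain[best$j] <- var_gain[best$j] + (cur_dev - best$dev)
    cur_dev <- best$dev
    basis <- cbind(basis, best$h)
    terms[[length(terms) + 1]] <- list(var = best$j, knot = best$t)
  }
  fit <- suppressWarnings(stats::glm.fit(basis, y01, family = stats::binomial()))
  list(coef = fit$coefficients, terms = terms, var_gain = var_gain)
}

predict_mars_logit <- function(fit, x) {
  B <- matrix(1, nrow(x), 1)
  for (tm in fit$terms)
    B <- cbind(B, pmax(x[, tm$var] - tm$knot, 0), pmax(tm$knot - x[, tm$var], 0))
  co <- fit$coef; co[is.na(co)] <- 0
  stats::plogis(drop(B %*% co))
}

# per-variable AUC filter importance for families with no native notion
auc_filter_importance <- function(x, y) {
  y01 <- as.numeric(y == "graduate")
  vapply(seq_len(ncol(x)), function(j) {
    a <- auc_roc(x[, j], y01); max(a, 1 - a)
  }, numeric(1))
}

fit_family <- function(x, y, config) {
  hp <- config$hyperparameters
  measures <- colnames(x)
  colnames(x) <- paste0("m", seq_len(ncol(x)))  # formula-safe internal names
  set.seed(config$seed)
  fit <- switch(config$family,
    GLM = suppressWarnings(stats::glm(y ~ ., data = data.frame(x, check.names = FALSE),
                                      family = stats::binomial())),
    LDA = MASS::lda(x, grouping = y),
    RR = glmnet::glmnet(x, y, family = "binomial", alpha = hp$alpha,
                        lambda = sort(unique(c(10, 1, 0.5, 0.2, hp$lambda,
                                               0.05, 0.01)), decreasing = TRUE)),
    PLS = fit_pls1(x, as.numeric(y == "graduate"), hp$ncomp),
    NB = e1071::naiveBayes(data.frame(x, check.names = FALSE), y),
    MARS = fit_mars_logit(x, as.numeric(y == "graduate"), hp$max_terms,
                          hp$n_knots),
    KNN = caret::knn3(x, y, k = hp$k),
    RF = randomForest::randomForest(x, y, ntree = hp$ntree))
  structure(list(family = config$family, fit = fit, config = config,
                 measures = measures, safe_names = colnames(x),
                 train_x = if (config$family %in% c("NB", "KNN")) x else NULL,
                 train_y = if (config$family %in% c("NB", "KNN")) y else NULL),
            class = "family_fit")
}

# probability of graduation for new dogs
predict_family <- function(object, x) {
  missing <- setdiff(object$measures, colnames(x))
  if (length(missing) > 0)
    stop("new cohort is missing measures used by the frozen model: ",
         paste(missing, collapse = ", "))
  x <- x[, object$measures, drop = FALSE]
  colnames(x) <- object$safe_names
  hp <- object$config$hyperparameters
  p <- switch(object$family,
    GLM = stats::predict(object$fit, newdata = data.frame(x, check.names = FALSE),
                         type = "response"),
    LDA = stats::predict(object$fit, x)$posterior[, "graduate"],
    RR = drop(stats::predict(object$fit, newx = x, s = hp$lambda,
                             type = "response")),
    PLS = predict_pls1(object$fit, x),
    NB = stats::predict(object$fit, data.frame(x, check.names = FALSE),
                        type = "raw")[, "graduate"],
    MARS = predict_mars_logit(object$fit, x),
    KNN = stats::predict(object$fit, x, type = "prob")[, "graduate"],
    RF = stats::predict(object$fit, x, type = "prob")[, "graduate"])
  unname(pmin(pmax(as.numeric(p), 0), 1))
}

raw_importance <- function(object) {
  fit <- object$fit
  safe <- object$safe_names
  out <- switch(object$family,
    GLM = {
      z <- summary(fit)$coefficients
      v <- abs(z[, "z value"]); v <- v[intersect(safe, names(v))]
      full <- stats::setNames(numeric(length(safe)), safe)
      full[names(v)] <- v; full
    },
    LDA = {
      v <- abs(fit$scaling[, 1]) * apply(fit$means, 2, stats::sd)
      v[safe]
    },
    RR = {
      co <- stats::coef(fit, s = object$config$hyperparameters$lambda)
      v <- abs(as.numeric(co))[-1]; names(v) <- rownames(co)[-1]
      v[safe]
    },
    PLS = stats::setNames(abs(fit$B), safe),
    NB = stats::setNames(auc_filter_importance(object$train_x, object$train_y),
                         safe),
    MARS = stats::setNames(fit$var_gain, safe),
    KNN = stats::setNames(auc_filter_importance(object$train_x, object$train_y),
                          safe),
    RF = randomForest::importance(fit)[, 1][safe])
  stats::setNames(as.numeric(out), object$measures)
}

# ---- screening and metrics --------------------------------------------------

#' Univariate logistic screening of cognitive measures
#'
#' Fits one single-predictor logistic regression of the binary training
#' outcome per measure (pairwise-complete) and ranks measures by ascending
#' Wald p-value. Measures that are constant, or observed fewer than twice in
#' either outcome class, are skipped with a warning; complete separation is
#' flagged rather than treated as an error.
#'
#' @param scores dogs x measures numeric matrix (`NA` allowed).
#' @param outcomes `"graduate"`/`"release"` labels (or 1/0), one per dog.
#' @return data.frame with columns `measure`, `coefficient`, `direction`,
#'   `p_value`, `degenerate`, `rank`, sorted by p-value.
#' @export
univariate_screen <- function(scores, outcomes) {
  y <- outcome_factor(outcomes)
  rows <- list()
  for (j in seq_len(ncol(scores))) {
    v <- scores[, j]; ok <- is.finite(v)
    if (length(unique(v[ok])) < 2 ||
        min(table(y[ok])) < 2 ||
        any(vapply(split(v[ok], y[ok]), function(g) length(g) < 2, logical(1)))) {
      warning("measure '", colnames(scores)[j], "' skipped in screening",
              call. = FALSE)
      next
    }
    degen <- FALSE
    fit <- withCallingHandlers(
      stats::glm(y[ok] ~ v[ok], family = stats::binomial()),
      warning = function(w) {
        if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
          degen <<- TRUE
        invokeRestart("muffleWarning")
      })
    co <- summary(fit)$coefficients
    rows[[length(rows) + 1]] <- data.frame(
      measure = colnames(scores)[j], coefficient = co[2, 1],
      direction = ifelse(co[2, 1] >= 0, "positive", "negative"),
      p_value = co[2, 4], degenerate = degen, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$p_value), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Threshold classification of predicted probabilities
#'
#' A dog is classified as a graduate when its predicted probability of
#' graduation is `>= threshold` (a probability exactly at the threshold
#' classifies as graduate — the documented tie rule).
#'
#' @param probabilities numeric vector in \[0, 1\].
#' @param threshold probability threshold (default 0.5).
#' @return character vector of `"graduate"` / `"release"`.
#' @export
classify_threshold <- function(probabilities, threshold = 0.5) {
  stopifnot(all(probabilities >= 0 & probabilities <= 1))
  ifelse(probabilities >= threshold, "graduate", "release")
}

#' Area under the ROC curve by concordance
#'
#' The probability that a randomly chosen graduate receives a higher
#' predicted probability than a randomly chosen release, with ties counted
#' one half; computed by the rank formula, so it is invariant to any strictly
#' increasing transform of the scores.
#'
#' @param probabilities numeric scores.
#' @param labels `"graduate"`/`"release"` or 1/0 labels.
#' @return AUC in \[0, 1\].
#' @export
auc_roc <- function(probabilities, labels) {
  y <- outcome_factor(labels)
  n_pos <- sum(y == "graduate"); n_neg <- sum(y == "release")
  if (n_pos == 0 || n_neg == 0) stop("both classes must be present")
  r <- rank(probabilities, ties.method = "average")
  (sum(r[y == "graduate"]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Quartile-stratified classification accuracy
#'
#' Dogs are ranked by predicted probability of graduation and assigned to
#' quartiles cut at the 25th/50th/75th sample percentiles (boundary ties go
#' to the lower quartile, except that dogs at the maximum probability always
#' belong to the 4th quartile, so the top quartile cannot be emptied by
#' ties). Accuracy is then computed within the 1st
#' (lowest-probability) and 4th (highest-probability) quartiles, comparing
#' threshold classifications against the true outcomes.
#'
#' @param probabilities predicted probabilities of graduation (>= 8 of them).
#' @param outcomes true `"graduate"`/`"release"` labels.
#' @param threshold classification threshold (default 0.5).
#' @return list with `q1_accuracy`, `q4_accuracy`, and `quartile`
#'   (integer 1-4 per dog).
#' @export
quartile_accuracy <- function(probabilities, outcomes, threshold = 0.5) {
  if (length(probabilities) < 8) stop("need at least 8 predictions")
  if (length(unique(probabilities)) == 1)
    stop("all probabilities identical: quartiles undefined")
  y <- as.character(outcome_factor(outcomes))
  cuts <- stats::quantile(probabilities, c(0.25, 0.5, 0.75), type = 7,
                          names = FALSE)
  q <- findInterval(probabilities, cuts, left.open = TRUE) + 1L
  q[probabilities == max(probabilities)] <- 4L
  lab <- classify_threshold(probabilities, threshold)
  acc_in <- function(idx) if (any(idx)) mean(lab[idx] == y[idx]) else NA_real_
  list(q1_accuracy = acc_in(q == 1L), q4_accuracy = acc_in(q == 4L),
       quartile = q)
}

#' Scale raw variable importances to 0-100 per model family
#'
#' Linear rescaling within each family so the least important measure scores
#' 0 and the most important 100. A family whose raw importances are all equal
#' is set to all 0 with a warning.
#'
#' @param raw numeric matrix, families x measures, of raw importances.
#' @return matrix of the same shape with values in \[0, 100\].
#' @export
scale_importance <- function(raw) {
  raw <- as.matrix(raw)
  out <- raw
  for (i in seq_len(nrow(raw))) {
    rng <- range(raw[i, ])
    if (diff(rng) == 0) {
      warning("all raw importances equal for family '", rownames(raw)[i],
              "'; set to 0", call. = FALSE)
      out[i, ] <- 0
    } else {
      out[i, ] <- 100 * ((raw[i, ] - rng[1]) / diff(rng))
    }
  }
  out
}

#' Compare predicted probabilities of graduates vs releases
#'
#' One-tailed Welch (unequal-variance) two-sample t-test of the predicted
#' probability of success, testing the alternative that graduates have the
#' higher predicted probability. Optionally restricted to dogs in the 1st and
#' 4th quartiles of predicted probability.
#'
#' @param probabilities predicted probabilities of graduation.
#' @param outcomes true `"graduate"`/`"release"` labels.
#' @param restrict `"all"` or `"q1_and_q4"`.
#' @return list with `t`, `df` (fractional, Welch-Satterthwaite), `p`
#'   (one-tailed), `n_graduate`, `n_release`.
#' @export
group_probability_ttest <- function(probabilities, outcomes,
                                    restrict = c("all", "q1_and_q4")) {
  restrict <- match.arg(restrict)
  y <- as.character(outcome_factor(outcomes))
  keep <- rep(TRUE, length(y))
  if (restrict == "q1_and_q4") {
    q <- quartile_accuracy(probabilities, outcomes)$quartile
    keep <- q %in% c(1L, 4L)
  }
  pg <- probabilities[keep & y == "graduate"]
  pr <- probabilities[keep & y == "release"]
  if (length(pg) < 2 || length(pr) < 2)
    stop("each outcome group needs at least 2 dogs after restriction")
  tt <- stats::t.test(pg, pr, alternative = "greater", var.equal = FALSE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, n_graduate = length(pg), n_release = length(pr))
}

# ---- cross-validation harness ----------------------------------------------

make_folds <- function(y, folds, stratified) {
  n <- length(y)
  assign <- integer(n)
  if (stratified) {
    for (cls in levels(y)) {
      idx <- sample(which(y == cls))
      assign[idx] <- rep_len(seq_len(folds), length(idx))
    }
  } else {
    assign[sample(n)] <- rep_len(seq_len(folds), n)
  }
  assign
}

#' Repeated stratified k-fold cross-validation of one model family
#'
#' Each repeat splits the dogs into `folds` folds (stratified by outcome by
#' default), fits the model on all but one fold and scores the held-out fold,
#' so every dog is scored out-of-fold exactly once per repeat. Accuracy, AUC,
#' and 1st/4th-quartile accuracies are computed within each held-out fold
#' (one iteration = one fold assessment); a split whose training part lacks a
#' class is re-drawn with a message. Fully reproducible from the scheme seed.
#'
#' @param scores complete dogs x measures numeric matrix (impute first).
#' @param outcomes `"graduate"`/`"release"` labels.
#' @param model a [model_config()].
#' @param scheme a [cv_scheme()].
#' @return a `cv_result`: list with `family`, `iterations` (data.frame with
#'   one row per fold x repeat), `summary` (means and SDs), and
#'   `resubstitution` (training-data accuracy and AUC).
#' @export
repeated_cv <- function(scores, outcomes, model, scheme = cv_scheme()) {
  y <- outcome_factor(outcomes)
  if (anyNA(scores)) stop("scores must be complete; run knn_impute() first")
  if (nlevels(droplevels(y)) < 2) stop("both outcome classes must be present")
  set.seed(scheme$seed)
  iter <- list()
  coverage_ok <- TRUE
  for (r in seq_len(scheme$repeats)) {
    repeat {
      assign <- make_folds(y, scheme$folds, scheme$stratified)
      ok <- all(vapply(seq_len(scheme$folds), function(f)
        nlevels(droplevels(y[assign != f])) == 2, logical(1)))
      if (ok) break
      message("re-randomizing a split with a single-class training fold")
    }
    seen <- integer(0)
    for (f in seq_len(scheme$folds)) {
      test <- which(assign == f)
      seen <- c(seen, test)
      fit <- fit_family(scores[-test, , drop = FALSE], y[-test], model)
      p <- predict_family(fit, scores[test, , drop = FALSE])
      truth <- as.character(y[test])
      acc <- mean(classify_threshold(p, model$threshold) == truth)
      auc <- if (nlevels(droplevels(y[test])) == 2) auc_roc(p, truth) else NA_real_
      qa <- tryCatch(quartile_accuracy(p, truth, model$threshold),
                     error = function(e) list(q1_accuracy = NA_real_,
                                              q4_accuracy = NA_real_))
      iter[[length(iter) + 1]] <- data.frame(
        repeat_index = r, fold = f, n_test = length(test), accuracy = acc,
        auc = auc, q1_accuracy = qa$q1_accuracy, q4_accuracy = qa$q4_accuracy)
    }
    if (!identical(sort(seen), seq_along(y))) coverage_ok <- FALSE
  }
  stopifnot(coverage_ok)
  iterations <- do.call(rbind, iter)
  full <- fit_family(scores, y, model)
  p_full <- predict_family(full, scores)
  summary <- list(
    accuracy = mean(iterations$accuracy),
    accuracy_sd = stats::sd(iterations$accuracy),
    auc = mean(iterations$auc, na.rm = TRUE),
    auc_sd = stats::sd(iterations$auc, na.rm = TRUE),
    q1_accuracy = mean(iterations$q1_accuracy, na.rm = TRUE),
    q4_accuracy = mean(iterations$q4_accuracy, na.rm = TRUE))
  structure(list(family = model$family, iterations = iterations,
                 summary = summary,
                 resubstitution = list(
                   accuracy = mean(classify_threshold(p_full, model$threshold) ==
                                     as.character(y)),
                   auc = auc_roc(p_full, as.character(y)))),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("%s: CV accuracy %.3f, CV AUC %.3f, q1 %.3f, q4 %.3f (%d iterations)\n",
              x$family, x$summary$accuracy, x$summary$auc,
              x$summary$q1_accuracy, x$summary$q4_accuracy,
              nrow(x$iterations)))
  invisible(x)
}

#' Fit the full eight-family ensemble on one cohort
#'
#' Models fitted here can be frozen and applied unchanged to an independent
#' cohort with [predict_ensemble()], mirroring the exploratory-then-prospective
#' workflow used in working-dog screening programs.
#'
#' @param scores complete dogs x measures numeric matrix.
#' @param outcomes `"graduate"`/`"release"` labels.
#' @param families subset of the eight family codes (default all).
#' @param threshold classification threshold shared by all families.
#' @param seed integer seed for stochastic fitters.
#' @return an `ensemble_fit`: list of `family_fit`s plus the scaled
#'   importance table (families x measures, 0-100).
#' @export
fit_ensemble <- function(scores, outcomes, families = model_families,
                         threshold = 0.5, seed = 1L) {
  y <- outcome_factor(outcomes)
  fits <- lapply(families, function(fam)
    fit_family(scores, y, model_config(fam, threshold = threshold, seed = seed)))
  names(fits) <- families
  raw <- do.call(rbind, lapply(fits, raw_importance))
  rownames(raw) <- families
  structure(list(fits = fits, importance = scale_importance(raw),
                 threshold = threshold, measures = colnames(scores)),
            class = "ensemble_fit")
}

#' Apply a frozen ensemble to a new cohort
#'
#' @param ensemble an [fit_ensemble()] result.
#' @param scores complete dogs x measures matrix containing every measure the
#'   frozen models use (extra measures are ignored); an informative error
#'   lists any missing ones.
#' @return matrix of predicted graduation probabilities, dogs x families.
#' @export
predict_ensemble <- function(ensemble, scores) {
  out <- vapply(ensemble$fits, predict_family, numeric(nrow(scores)),
                x = scores)
  if (is.null(dim(out))) out <- matrix(out, nrow = 1,
                                       dimnames = list(NULL, names(ensemble$fits)))
  rownames(out) <- rownames(scores)
  out
}
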