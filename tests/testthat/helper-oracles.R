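# Independent brute-force oracles used to cross-check the implementation.

# AUC by enumerating all graduate/release pairs (ties count one half)
oracle_auc_pairs <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) for (q in neg)
    total <- total + if (p > q) 1 else if (p == q) 0.5 else 0
  total / (length(pos) * length(neg))
}

# exhaustive kNN imputation: plain loops, no vectorization shared with the
# implementation
oracle_knn_impute <- function(m, k) {
  n <- nrow(m); p <- ncol(m)
  mu <- colMeans(m, na.rm = TRUE)
  sg <- apply(m, 2, sd, na.rm = TRUE); sg[!is.finite(sg) | sg == 0] <- 1
  z <- m
  for (j in 1:p) z[, j] <- (m[, j] - mu[j]) / sg[j]
  out <- m
  for (i in 1:n) for (j in 1:p) {
    if (!is.na(m[i, j])) next
    d <- rep(Inf, n)
    for (i2 in 1:n) {
      if (i2 == i || is.na(m[i2, j])) next
      shared <- which(!is.na(m[i, ]) & !is.na(m[i2, ]))
      if (length(shared) == 0) next
      d[i2] <- mean((z[i, shared] - z[i2, shared])^2)
    }
    nn <- order(d)[1:k]
    out[i, j] <- mean(m[nn, j])
  }
  out
}

# Welch two-sample t from the textbook formulas
oracle_welch <- function(a, b) {
  va <- var(a) / length(a); vb <- var(b) / length(b)
  t <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  list(t = t, df = df, p_greater = pt(t, df, lower.tail = FALSE))
}

# one-sample t from the textbook formula
oracle_one_sample_t <- function(x, mu = 0) {
  t <- (mean(x) - mu) / (sd(x) / sqrt(length(x)))
  list(t = t, df = length(x) - 1,
       p_two = 2 * pt(-abs(t), length(x) - 1))
}

# OLS residuals via the normal equations
oracle_ols_residuals <- function(y, x) {
  X <- cbind(1, x)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  as.numeric(y - X %*% beta)
}

# small complete toy score matrix with DCTB-vocabulary names
toy_scores <- function(n = 12, p = 4, seed = 42) {
  set.seed(seed)
  nm <- c("odor discrimination", "arm pointing", "working memory",
          "inferential reasoning", "cylinder", "marker cue")[1:p]
  matrix(rnorm(n * p), n, p,
         dimnames = list(sprintf("dog_%03d", 1:n), nm))
}
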