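---
title: "Linking dog cognition to working-dog outcomes: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Linking dog cognition to working-dog outcomes: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(caninecog)
```

`caninecog` implements two complementary designs for relating individual
differences in dog cognition — scores from a multi-task battery such as the
25-task Dog Cognition Test Battery (DCTB) — to success as a working dog.
This vignette explains the models and procedures, the tunable parameters and
their defaults, the synthetic data the tests rely on, and the numerical and
design choices made where the methods left room.

## Cohort data and exclusion accounting

Cohorts arrive as a roster (one row per dog: sex, breed, age, program status
flags, optional graduate/release outcome) plus a dogs × measures score
matrix. Measure names are matched case-insensitively after dash and
whitespace normalization against a controlled vocabulary
(`dctb_measures()`), with parenthetical sub-measure suffixes such as
`"unsolvable task (look at experimenter)"`; unknown names are errors rather
than silently dropped columns, because a typo in a measure name should never
silently shrink an analysis.

Analytic samples are assembled with explicit exclusion rules
(`apply_exclusions()`): status-flag removals (e.g. transfer to a different
program, medical release), dogs that aborted more than a permitted number of
battery tasks, and dogs missing more than a permitted number of predictor
measures. Rules apply in their listed order and each dog is removed by at
most one rule — the first that matches — so the report always reconciles
exactly (`initial_n = final_n + sum(removed)`). Status-based rules are
conventionally listed before data-completeness rules; when a dog qualifies
for several removals the report attributes it to the earliest listed rule,
and the report format makes that precedence explicit rather than ambiguous.

## Preprocessing

**Box-Cox transform** (`boxcox_fit()`/`boxcox_apply()`). Many battery scores
are skewed proportions or counts. The exponent λ is estimated by maximizing
the profile log-likelihood with a continuous search (`optimize()` on
[−5, 5]), not a fixed grid, for reproducibility. Scores that can be zero or
negative are shifted by `1 − min` before fitting (shift 0 when already
positive). λ numerically at zero uses the log branch. Binary or
near-constant measures skip the transform with a warning — a power transform
is undefined or meaningless there. The mapping is strictly monotone, so rank
statistics are unaffected.

**kNN imputation** (`knn_impute()`, default `k = 5`). Distances between dogs
are mean squared differences over the measures observed in *both* dogs,
computed on per-measure standardized values; each missing cell is the
unweighted mean of the k nearest dogs among those observing that measure.
Observed cells are never altered; the procedure is deterministic (distance
ties break by row order). `k = 5` is a conventional small-neighbourhood
default for cohorts of ~100 dogs; the method, not the k, is what the
workflow specifies, and k is logged in the frozen preprocessing config.

A fitted preprocessing state (per-measure shift/λ plus k) can be written to
a plain-text config (`write_preprocess_config()`) and re-applied unchanged
to an independent cohort. Whether to freeze or refit on the new cohort is an
explicit switch (`refit_preprocess` in `run_experiment1()`, default:
frozen, matching the frozen-model philosophy of the prospective design).
When frozen transforms meet a new-cohort value below the training support,
the value is clipped to the edge of the positive domain rather than
erroring, the same convention prediction-time preprocessors typically use.

**Quantile discretization** (`discretize_quantiles()`): two categories split
at the median, three at the 33.3rd/66.7th percentiles
(linear-interpolation sample quantiles, type 7). Values tied with a boundary
go to the lower category — a fixed, documented rule, since with heavily tied
behavioural scores *some* convention is needed for reproducibility.
Discretization is invariant to strictly increasing transforms of the input,
which is why running it after Box-Cox changes nothing.

## The classifier ensemble and its evaluation

Eight model families are evaluated in parallel: GLM (logistic regression),
LDA, ridge-regularized logistic regression (RR), partial least squares
(PLS), naive Bayes (NB), adaptive regression splines (MARS), k-nearest
neighbours (KNN), and random forest (RF). What this package owns — and what
is contract-tested — is the evaluation harness: the resampling scheme, the
threshold rule, quartile stratification, importance scaling, and the group
comparisons. The family internals are standard: `stats::glm`, `MASS::lda`,
`glmnet` (ridge at a fixed λ = 0.1, since hyperparameter tuning is
deliberately out of scope), `e1071::naiveBayes`, `caret::knn3` (7
neighbours, the stated working value for this design), and
`randomForest` (500 trees). Two families are implemented in-package because
no suitable backend is among the package's dependencies: PLS as NIPALS PLS1
regression of the 0/1 outcome on standardized predictors (2 components by
default, predictions clamped to [0, 1]), and MARS as forward-stagewise
selection of hinge-function pairs by binomial deviance reduction, refit as a
single logistic model (at most 9 basis columns, 7 candidate knots per
variable). All hyperparameters are recorded in the run manifest.

**Cross-validation** (`repeated_cv()`): stratified k-fold (default 4 folds ×
100 repeats; the examples and tests in this package use 1–20 repeats to keep
them quick — the estimator is the same). Stratification keeps the class
ratio per fold within one dog. Each fold assessment is one *iteration*;
accuracy, AUC and the two quartile accuracies are computed within each
held-out fold, and every dog is scored out-of-fold exactly once per repeat
(asserted at run time). A split whose training part loses a class is
re-drawn with a message. Everything is reproducible from the scheme seed.

**Threshold and quartiles.** A dog is classified graduate when
p̂ ≥ 0.5; a probability exactly at the threshold classifies as graduate
(documented tie rule). For quartile-stratified accuracy, dogs are cut at the
25th/50th/75th percentiles of p̂ with boundary ties going to the lower
quartile, except that dogs at the maximum p̂ always belong to the 4th
quartile — otherwise a heavily tied top (e.g. many p̂ = 1) would empty the
quartile whose accuracy is the design's headline quantity. The 4th quartile
is the *highest* predicted probability of success; where summaries of this
design have labelled quartile rows inconsistently, this package follows the
definition "4th = highest p̂, expected most accurate".

**AUC** is computed by the rank (concordance) formula with ties counted one
half, so it is invariant to monotone transforms of the scores; tests verify
it against brute-force pair counting and an independent ROC implementation.

**Variable importance.** Each family contributes its conventional raw
importance notion (|z| of coefficients for GLM, standardized discriminant
weights for LDA, |coefficients| for RR/PLS, deviance gain for MARS, Gini
decrease for RF, and a per-variable AUC filter for NB/KNN, which have no
native notion). Raw importances are then linearly rescaled within family to
0–100 (min → 0, max → 100). Only the scaling and the cross-family consensus
ranking are contracted; raw values are implementation-conventional and not
comparable across libraries.

**Group comparisons** (`group_probability_ttest()`): one-tailed Welch
t-tests of p̂ for graduates vs releases (optionally restricted to the 1st ∪
4th quartiles). Welch was chosen because the design's reported comparisons
carry fractional degrees of freedom, which only the unequal-variance test
produces.

A note on null behaviour: with labels independent of all measures,
out-of-fold AUC is *slightly pessimistic* (below 0.5) when the predictor
count is large relative to n, because a model that fits noise
anti-generalizes. This is a property of the estimator, not a bug; the
package's null-calibration test therefore uses few predictors relative to n,
where the effect is negligible.

## Scoring detection-dog performance records

- **Training logs** (`score_training_logs()`): weekly 0–3 prevalence scores
  per behavioural category (handling, temperament, motivation, handler
  dependence, odor recognition, odor response, false responses). Weeks
  reporting ≤ 2 training days are excluded from numerator *and* denominator.
  The ratio score is the category's summed prevalence over eligible weeks
  divided by the number of eligible weeks (higher = more problems), so
  duplicating every eligible week leaves it unchanged.
- **Duration adjustment** (`adjust_for_duration()`): when ratio scores
  correlate with how long a dog was observed, they are regressed on the
  number of scored weeks and the residuals are multiplied by −1 so higher
  values mean better performance. The adjusted scores sum to zero and are
  exactly uncorrelated with the week counts. With a constant week count the
  slope is unidentifiable; that is an error unless the caller explicitly
  opts into plain negated centering.
- **Ordinal rating series** (`weighted_ordinal_score()`): percent of records
  at each rating (0–100 scale) × weights excellent = 1, good = 0.66,
  fair = 0.33, poor = 0, summed. The published weights are 0.66/0.33, not
  2/3 and 1/3 — fidelity over tidiness — and the 0–100 percentage scale is
  forced by the stated bounds (all-poor → 0, all-excellent → 100). The score
  is monotone: upgrading any single record never decreases it.
- **Post-deployment evaluations** (`percent_passed()`): percent of passed
  items per category.
- **Assembly** (`assemble_performance_table()`): one wide dogs × measures
  table with an availability mask (data availability varies widely across
  record types) and a declared orientation per measure. Lower-is-better
  measures (raw log ratios) are sign-flipped in the normalization pass so
  that downstream "positive association" uniformly means "higher cognition
  score ↔ better performance". The orientation map is explicit config, not
  inference.

## The directional consensus screen

Every cognitive measure is tested against every available performance
measure after discretization: a two-sample t-test for two categories (Welch
by default; pooled variance is a config switch, since either is defensible)
or a one-way ANOVA for three. Significance is judged at α = 0.05 with **no
multiple-testing correction — deliberately**. The screen's logic is that
with hundreds of tests many false positives are certain, but false positives
should be *directionally random*; the information is in the directional
consensus, not in any single p-value. Each significant association is
annotated: positive/negative by which performance group has the higher mean
cognition score, or, for ANOVAs, by the sign of (top-category mean −
bottom-category mean) when the ordered group means are weakly monotone (ties
allowed at one junction) and *neutral* otherwise — e.g. when below- and
above-average dogs look alike but the middle group deviates.

Per cognitive measure, `aggregate = n_positive − n_negative` (neutral
counts 0). `consensus_null_test()` then tests the aggregates against 0 with
a two-tailed one-sample t-test: under direction-randomness the mean
aggregate should be indistinguishable from zero even when the mean *number*
of associations per measure is well above what α alone would produce.
Battery selection keeps measures with |aggregate| ≥ 3 (default) plus any
manual includes, which are flagged as such — a simple, fast task can earn a
place on practical grounds.

Performance measures derived from a common source (e.g. the seven
training-log categories) each count as separate associations; the aggregate
is a vote count, not an independence-weighted statistic, and the null test
exists precisely to calibrate expectations about it.

## Replication statistics

For each retained predictor, `beta_panel()` fits one linear model per
performance outcome with predictor and outcome z-scored, so each β is the
standardized slope (equal to Pearson's r in this single-predictor case) on
its own pairwise-complete sample — availability varies per outcome and
`n_used` is recorded. `beta_panel_test()` runs a one-tailed one-sample
t-test on the panel (t = mean/SEM, df = n_outcomes − 1) in the direction
carried over from the exploratory screen; a panel whose mean opposes its
hypothesis yields p > 0.5, and the two opposite one-tailed p-values always
sum to 1. Note that t cannot generally be recovered from *rounded*
mean/SEM summaries (e.g. a printed 0.07/0.03 alongside t = 2.19); the
contract is t = mean/SEM on unrounded inputs, and such rounding
inconsistencies in published summaries are documented, not "fixed".
Inter-rater reliability of the human coding steps is covered by
`cohen_kappa()` (marginal-product chance correction; κ defined as 1 when
both raters are constant and identical) and `pearson_r()`.

## Synthetic cohorts: what they emulate, and what they do not

`synthetic_config()` + `simulate_cohort()` generate cohorts with the
structure the analyses assume: cognitive scores from a latent factor model
(individual differences in dog cognition are multi-factorial, so the default
is 11 measures loading 0.7 on three factors with unique noise 0.7);
graduation outcomes from a logit model whose intercept is root-solved so the
expected base rate hits the target within 0.01 (defaults 0.68 for
exploratory-style and 0.77 for prospective-style cohorts, the two observed
graduation rates in this design's populations); a scalar latent "detection
quality" per dog driving training logs (mean 33 weeks per dog, 1–5 reported
days so some weeks are ineligible, ordered-logit 0–3 prevalence scores whose
severity falls with quality) and ordinal rating series (ordered logit,
~97 records per dog); optional planted correlations between named measures
and quality; and independent cell-wise missingness. All randomness flows
from one root seed through named substreams, so each stage is independently
reproducible.

What the generator does *not* emulate: the real DCTB factor loadings (never
published for this design; loadings are user parameters), coder subjectivity
and drift in the prose-log scoring, informative missingness (dogs missing
data *because* they struggled), and cohort drift between exploratory and
prospective populations beyond the base-rate shift. Passing tests on
synthetic cohorts therefore demonstrate that the machinery recovers the
structure it assumes — calibrated nulls, recoverable planted effects,
conservation and determinism — not that real cohorts satisfy those
assumptions.

## Numerical choices and degenerate inputs

- Ties: threshold ties classify graduate; quartile boundary ties go low
  (max-p̂ dogs always 4th quartile); discretization boundary ties go low;
  kNN distance ties break by row order. All arbitrary, all fixed.
- Constant or near-constant measures: skipped by Box-Cox and by the
  univariate screen (with warnings); errors for z-scores, standardized
  betas, and correlation.
- Complete separation in the univariate logistic screen is flagged
  (`degenerate = TRUE`) rather than treated as a crash or a trustworthy
  p-value.
- Single-class training folds are re-randomized with a message; held-out
  folds with one class contribute accuracy but not AUC.
- Importance scaling divides before multiplying by 100 so the family maximum
  is exactly 100 in floating point.
- The association grid marks (cognitive, performance) pairs whose categories
  are emptied by missingness as unavailable instead of erroring, mirroring
  the patchy availability of real performance records.

## Problem sizes used in the shipped tests

The test suite runs the full machinery at reduced scale, chosen as the
smallest sizes at which each property is sharply testable: cross-validation
with 1–20 repeats on cohorts of 32–120 dogs; null calibration with 500
replicates of a 20-measure × 8-outcome screen on 60 dogs and 500 zero-effect
beta panels; effect recovery with 100 replicates at n = 150 and planted
correlation 0.6, and 20 replicates of a planted logit signal
(two coefficients of 1.1 on 11 measures, n = 120, base rate 0.68). The
acceptance script reproduces the self-contained published arithmetic
(aggregate scores from the bundled count table; ordinal score bounds)
exactly.

## Known limitations

- The ridge λ and the PLS/MARS structural parameters are fixed defaults, not
  tuned; this matches the design's scope (model comparison under a shared
  harness), but absolute CV numbers will vary with these choices.
- Raw importances are family-conventional; only their 0–100 scaling and the
  consensus ranking are meaningful across families.
- The consensus aggregate treats correlated performance measures as
  independent votes; its null test calibrates the sign, not the count.
- With strong class imbalance and small folds, quartile accuracies inside a
  held-out fold are computed on very few dogs and are accordingly noisy;
  they stabilize through repetition, which is the point of 100 repeats.
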