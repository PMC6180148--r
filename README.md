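# caninecog

Cognitive test batteries and outcome prediction for working dogs.

Only a fraction of the dogs bred and trained as assistance or explosive
detection dogs ultimately succeed, and screening has traditionally relied on
temperament. `caninecog` implements the two statistical workflows used to ask
whether *cognitive* individual differences — measured with a multi-task
battery such as the 25-task Dog Cognition Test Battery (DCTB) — predict
working-dog outcomes:

1. **Predictive modelling of a binary training outcome** (assistance dogs:
   graduate vs release). Cognitive scores are Box-Cox transformed and
   kNN-imputed, then an ensemble of eight classifier families (GLM, LDA,
   ridge regression, PLS, naive Bayes, adaptive regression splines, kNN,
   random forest) is evaluated by stratified 4-fold cross-validation repeated
   100 times. A dog is classified as a graduate when its predicted
   probability of graduation p̂ ≥ 0.5. Besides overall accuracy and ROC AUC,
   the package computes **quartile-stratified accuracy**: accuracy within the
   1st (lowest p̂) and 4th (highest p̂) quartiles of predicted probability —
   the key applied quantity, since predictions are most reliable for dogs
   predicted most likely to succeed. Fitted models are frozen and applied
   unchanged to an independent prospective cohort, where graduates and
   releases are compared with one-tailed Welch t-tests on p̂.

2. **Directional consensus screening with replication** (detection dogs,
   which have no single success metric). Heterogeneous performance records —
   weekly training-log prevalence scores turned into per-category ratio
   scores, ordinal excellent/good/fair/poor series scored with weights
   1/0.66/0.33/0, survey and pass/fail evaluations — are discretized into
   quantile categories and each cognitive measure is tested against each
   (t-test or 3-group ANOVA, α = 0.05 **uncorrected**). Each significant
   association is annotated +1 (positive), −1 (negative) or 0 (neutral,
   a significant but non-monotone 3-group pattern), and per measure the
   **aggregate score** is

   `aggregate = n_positive − n_negative`.

   False positives are expected, but their directions should be random, so
   only measures with a consistent directional consensus (|aggregate| ≥ 3)
   are retained for a short-format battery. A one-sample t-test of the
   aggregates against 0 checks the sign-randomness null. In the replication
   cohort, each retained measure gets a panel of standardized regression
   coefficients (z-scored predictor and outcome, so β = Pearson r) across
   the available performance measures, tested with a one-tailed one-sample
   t-test in the direction hypothesized from the exploratory screen.

A synthetic cohort generator (latent-factor cognitive scores, logit outcomes
with a calibrated base rate, quality-driven training logs and rating series)
makes every stage testable end to end; inter-rater reliability helpers
(Cohen's κ, Pearson r) cover the record-coding steps.

## Worked example

The package bundles the per-measure counts of significant directional
associations from an exploratory detection-dog screen of the full battery:

```r
library(caninecog)
agg <- aggregate_from_counts(detection_screen_counts())
head(agg[order(-agg$aggregate), ], 4)
#>          cognitive_measure total n_negative n_neutral n_positive aggregate
#>        odor discrimination     5          0         0          5         5
#>                 marker cue     5          0         0          5         5
#>  causal reasoning (visual)     4          0         0          4         4
#>               arm pointing     4          0         0          4         4

cs <- consensus_null_test(agg)
sprintf("mean aggregate %.1f +/- %.1f; t(%d) = %.2f, p = %.2f",
        cs$mean_aggregate, cs$sem_aggregate, cs$df, cs$t, cs$p)
#> "mean aggregate 0.4 +/- 0.4; t(28) = 0.86, p = 0.40"
```

So across 29 cognitive measures there were on average 3.2 ± 0.4 significant
associations each, but the mean aggregate (0.4 ± 0.4) is indistinguishable
from the sign-randomness null — individual significant associations carry
little information here. Selection therefore keeps only the directionally
consistent measures (plus any manually retained simple task):

```r
select_short_battery(agg, threshold = 3,
                     manual_includes = "laterality: object manipulation")
#>                       cognitive_measure aggregate    reason
#>                     odor discrimination         5 aggregate
#>                              marker cue         5 aggregate
#>               causal reasoning (visual)         4 aggregate
#>                            arm pointing         4 aggregate
#>                      memory-distraction         3 aggregate
#>                          working memory         3 aggregate
#>  unsolvable task (manipulate container)        -6 aggregate
#>         laterality: object manipulation        -2    manual
```

Seven measures pass the |aggregate| ≥ 3 rule — six with consistently
positive associations and one (manipulating the container in the unsolvable
task, i.e. persistence instead of help-seeking) consistently negative.

For the predictive workflow on a simulated cohort, see
`?run_experiment1` and the vignette (`vignettes/working-dog-cognition.Rmd`).

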