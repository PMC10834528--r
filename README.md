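# upliftRCT

Uplift modeling for treatment-benefit stratification in two-arm randomized
trials, built around the question that motivated it: which patients with
persistent atrial fibrillation need extensive catheter ablation on top of
pulmonary vein isolation, when the trial shows no clear benefit on average?

The package implements the one-model (class-variable transformation)
uplift method end to end:

* **Scoring.** Relabel each subject with
  `Z = 1` for treated successes and control failures, fit one probabilistic
  classifier for `P(Z = 1 | X)`, and score each subject's individual
  treatment effect as `u(X) = P_T(Y=1|X) − P_C(Y=1|X) = 2 P(Z=1|X) − 1`
  (exact under 1:1 randomization).
* **Selection.** Rank subjects by descending score and build the Qini curve
  `Qini(φ) = S_T(φ) − S_C(φ) N_T(φ)/N_C(φ)` over cumulative successes and
  counts above each threshold. The candidate classifier with the largest
  Qini coefficient (area between curve and random-allocation diagonal) on a
  held-out validation split wins, and the score at the rank maximizing the
  curve's lead over the diagonal becomes the cutoff `φ*`.
* **Validation.** On an untouched test split, compare arms within the
  `score ≥ φ*` and `score < φ*` strata: Kaplan–Meier curves, log-rank,
  unadjusted Cox hazard ratios with 95% CIs, the treatment-by-stratum
  interaction, Schoenfeld diagnostics, and baseline-characteristics tables
  (Fisher exact / Mann–Whitney).

Because trial data of this kind are not public, the package ships a seeded
synthetic two-arm trial generator with known, covariate-dependent planted
benefit, so every stage can be validated against ground truth. Nine
classifier families are built in (logistic regression, decision tree,
random forest, adaptive boosting, gradient boosting, naive Bayes, k-nearest
neighbours, linear/quadratic discriminant analysis) behind a pluggable
registry.

Audience: biostatisticians and clinical data scientists analyzing
randomized trials for heterogeneous treatment effects.

## Worked example

The `analysis/` scripts run the whole workflow on a 497-subject synthetic
cohort split 249/248 by registration order, with the training half split
again 124/125 (train / Qini validation):

```sh
Rscript analysis/01_simulate_cohort.R
Rscript analysis/02_fit_uplift_models.R
Rscript analysis/03_evaluate_test_set.R
Rscript analysis/04_robustness_checks.R
```

Step 2 prints the validation Qini ranking over all nine candidates
(seed 1):

```
model selection (validation Qini coefficients):
          classifier_id qini_coefficient optimal_cutoff
    logistic_regression       271.414489     0.07420859
    linear_discriminant       266.078919    -0.02831983
            naive_bayes       261.356495    -0.99990387
      gradient_boosting       229.669562     0.51698685
      adaptive_boosting       200.485062     0.37756139
          random_forest        82.795911     0.08400000
          decision_tree        37.544030     0.50000000
   k_nearest_neighbours        22.414736     0.60000000
 quadratic_discriminant        -9.369127     0.99185365

selected: logistic_regression with cutoff 0.0742
```

The winner's cutoff stratifies the 248-subject test half (step 3), and the
high stratum is genuinely enriched for planted benefit — mean true uplift
0.013 versus −0.120 in the low stratum. With only ~27 events per stratum a
single trial-scale run is noisy, though; step 4 shows what the workflow
does at scale (30 replicates, n = 2000 each):

```
recovery replicates (n = 2000 each):
  high-stratum HR < low-stratum HR in 100% of 30 replicates
  median high-stratum HR 0.77, median low-stratum HR 1.73

null-calibration replicates (benefit_scale = 0):
  interaction p: 3% below 0.05; KS uniformity p = 0.62
```

i.e. the selected cutoff reliably concentrates the treatment benefit in the
high stratum, and with no planted heterogeneity the pipeline does not
manufacture subgroups from noise.

The same machinery is available programmatically:

```r
library(upliftRCT)
report <- run_pipeline(paper_shape_config(seed = 1))
report$model_selection       # per-classifier Qini coefficients
report$comparisons$high      # within-stratum HR, CI, p-values
export_report(report, "results/evaluation")
```

## Layout

* `R/` — the package: cohort I/O and registration-order splits, the
  synthetic generator, leakage-safe preprocessing, the classifier registry,
  uplift scoring, Qini machinery, survival evaluation, pipeline
  orchestration.
* `analysis/` — numbered narrative drivers over the package functions.
* `vignettes/uplift-workflow.Rmd` — the model, its assumptions, numerical
  conventions, generator design and limitations.
* `tests/testthat/` — unit, property and end-to-end suites with
  independent oracles.
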