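---
title: "Uplift modeling for treatment-benefit stratification: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Uplift modeling for treatment-benefit stratification: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

A randomized trial can show that an intensified treatment is *not better on
average* and still conceal a subgroup that benefits substantially. The
motivating setting is catheter ablation for persistent atrial fibrillation:
adding extensive substrate ablation (linear and/or CFAE lesions) to pulmonary
vein isolation helps some patients and not others, and trials comparing the
strategies head-to-head have been inconclusive. `upliftRCT` implements a
workflow for finding the benefiting subgroup from two-arm randomized data:
score every subject's *individual* treatment effect with a single
classification model, pick the model and a score cutoff on held-out
validation data using Qini curves, and then confirm on an untouched test set
that subjects above the cutoff actually do better under the intensified
treatment.

## The one-model uplift method

Let $X_i$ be a subject's baseline covariates, $Y \in \{0, 1\}$ the success
indicator (1 = no recurrence within the 12-month follow-up), and $T/C$ the
randomized arms. The estimand is the uplift score

$$u(X_i) = P_T(Y = 1 \mid X_i) - P_C(Y = 1 \mid X_i),$$

the gain in success probability attributable to the intensified treatment.
Rather than fitting one model per arm, the class-variable transformation
defines

$$Z = \begin{cases} 1 & \text{treatment arm and success} \\
                    1 & \text{control arm and failure} \\
                    0 & \text{otherwise,} \end{cases}$$

and fits a single probabilistic classifier for $P(Z = 1 \mid X_i)$. Under
two assumptions — allocation independent of $X_i$, and equal probability of
assignment to either arm — the identity

$$u(X_i) = 2\,P(Z = 1 \mid X_i) - 1$$

holds, so one classifier recovers the uplift score. Both assumptions are
guaranteed by 1:1 randomization. The package asserts the second only
approximately (blocked allocation gives $|n_T - n_C| \le 1$); with truly
imbalanced arms the identity is biased, which is why `compute_qini_curve()`
and everything downstream work on *ranks* of the score, not its absolute
scale. The identity is verified exactly in the test suite on a
discrete-covariate fixture with exact 1:1 allocation per level, where the
frequency-oracle classifier makes both sides computable by hand.

Classifier probability calibration is deliberately not enforced. A poorly
calibrated classifier distorts the score scale (and therefore the numeric
value of a cutoff) but not the ranking, and both model selection and cutoff
choice are rank-based.

## Qini curves, model selection and the cutoff

Subjects are sorted by descending score. At threshold $\varphi$, with
$S_T(\varphi), S_C(\varphi)$ the cumulative successes and $N_T(\varphi),
N_C(\varphi)$ the cumulative counts among subjects scoring $\ge \varphi$,

$$\mathrm{Qini}(\varphi) = S_T(\varphi) -
  \frac{S_C(\varphi)\, N_T(\varphi)}{N_C(\varphi)}.$$

The horizontal axis is rank, not the score itself. The diagonal reference is
the chord from $(0, 0)$ to $(n, \text{final incremental success})$ — what a
random ordering would earn on average. The Qini coefficient is the
trapezoidal area between curve and diagonal; the candidate with the largest
coefficient on the validation split wins, with exact ties broken by registry
order so selection is deterministic.

Numerical choices that had to be pinned down:

* **Ties.** Tied scores are processed as one block and the curve is recorded
  only at block boundaries, making it invariant to the arbitrary ordering of
  tied subjects.
* **The $N_C = 0$ prefix.** Before the first control subject enters, the
  control correction is undefined; the curve takes its limit $S_T$ and the
  points are flagged `control_prefix`.
* **Cutoff.** $\varphi^*$ is the score at the rank maximizing
  $\mathrm{Qini} - \mathrm{diagonal}$, ties toward the smaller rank (the
  stricter cutoff). Maximizing this lead — rather than minimizing the
  reverse difference — is the convention of the uplift literature and the
  only reading consistent with the cutoff's purpose, since the reverse
  selects the *worst* targeting depth; the package standardizes on it.
* **No benefit.** If the maximum lead is $\le 0$ nothing beats random
  targeting; the cutoff is $+\infty$ with a `no_benefit` flag, the high
  stratum is empty and downstream reporting warns instead of failing.
* **Normalization.** The coefficient is reported as the raw area on the rank
  axis; `qini_coefficient(normalize = TRUE)` divides by $n$ for
  cross-cohort comparison. Raw coefficients are therefore comparable only
  within one validation cohort.

```{r}
library(upliftRCT)
report <- run_pipeline(paper_shape_config(seed = 1))
report$model_selection
```

## Preprocessing

Fitted on the model-training split only and replayed, frozen, on validation
and test data — the recipe never reads statistics from the cohort it
transforms, so held-out data cannot leak into preparation. The original
analysis does not state where its preprocessing statistics were computed;
the leakage-safe order is this package's choice.

| step | rule | default |
|---|---|---|
| missingness screen | drop a feature iff missing fraction **strictly** exceeds the threshold | 0.15 |
| imputation | continuous: training mean; categorical: constant level `"not available"`, kept as an ordinary one-hot level | — |
| correlation pruning | within each connected group of continuous features with pairwise \|r\| > threshold, keep the highest-priority feature | 0.7 |
| robust scaling | $(x - \mathrm{median}) / \mathrm{IQR}$, quantile type 7 | — |

"Most informative" among correlated features is a clinical judgement, not a
computable rule, so `prune_correlated()` demands an explicit `keep_priority`
list whenever a correlated group exists and refuses to choose silently.
Correlation is Pearson's r on imputed continuous pairs; categorical features
are excluded because r is undefined for unordered levels. The type-7
(linear-interpolation) quartile convention is pinned so scaling is
bit-reproducible; a zero-IQR feature is centered only, with a warning.

## The classifier registry

Nine families are built in — logistic regression, decision tree, random
forest, adaptive boosting, gradient boosting, naive Bayes, k-nearest
neighbours, linear and quadratic discriminant analysis — spanning linear,
instance-based, Bayes, discriminant and tree/boosting learners, including
adaptive boosting, the family the motivating analysis selected. The
adaptive-boosting learner is implemented in the package: discrete AdaBoost
over weighted `rpart` stumps, with probabilities through the logistic link
on the ensemble margin, $P(Z=1|x) = (1 + e^{-2F(x)})^{-1}$. Other families
wrap `stats::glm`, `rpart`, `randomForest`, `xgboost`, `e1071`,
`caret::knn3` and `MASS`. Hyperparameters default to the widely documented
library defaults, are fully exposed through `fit_uplift_model()`, and no
tuning loop is run. Further families (SVM, Gaussian process, extra trees,
the gradient-boosting variants) can be added with `register_classifier()`
without touching the pipeline, which is family-agnostic.

Gini (impurity-decrease) importance is available for the tree ensembles;
one-hot importances are aggregated back to source features (a categorical
feature's dummy columns sum into one entry) and normalized to sum to 1.
Discriminant fits reduce the design to a full-rank column set first (QR
pivoting, per class for QDA) so collinear one-hot blocks cannot make a
covariance singular.

## Survival validation

Within each test-set stratum (`high`: score $\ge \varphi^*$, closed at the
cutoff; `low` otherwise) the arms are compared by intention to treat:
Kaplan–Meier curves, the log-rank test, and the unadjusted Cox hazard ratio
with Wald 95% CI. Ties use Efron's method. Because the within-stratum
p-value can be attributed to either the Cox Wald test or the log-rank test,
both are computed and labelled. The treatment-by-stratum interaction is the
Wald test of the product term in
`Surv ~ treatment + stratum + treatment:stratum`, and the
proportional-hazards assumption is checked per term via scaled Schoenfeld
residuals (`pass` at p > 0.05). Characteristic tables render continuous
rows as `median [Q1, Q3]` with Mann–Whitney p-values and categorical rows
as `n (%)` with Fisher exact p-values — the probability-summation two-sided
Fisher convention, and Mann–Whitney with exact enumeration when the
combined sample is $\le 20$ without ties, otherwise the tie-corrected
normal approximation without continuity correction (so identical samples
give p = 1).

## The synthetic trial generator

Real trial data of this kind are not public, so every end-to-end claim is
validated against a seeded generator with known ground truth. Defaults
emulate a persistent-AF ablation trial: $n \approx 500$; blocked 1:1
allocation drawn independently of covariates; eight continuous covariates
(clinical measures roughly normal, labs log-normal) and fourteen binary
history items at realistic prevalences; control-arm success
$\mathrm{logit}^{-1}(\eta_i)$ centered at 74% (20–30% 1-year recurrence);
and MCAR missingness at a few percent on selected labs. The planted benefit
adds $b_i = \text{benefit\_scale} \times$ a linear combination of
standardized covariates (by default: female sex and larger atria increase
benefit; smoking, higher hemoglobin and higher natriuretic peptide decrease
it) to the logit, so

$$u_i = \mathrm{logit}^{-1}(\eta_i + b_i) - \mathrm{logit}^{-1}(\eta_i)$$

is bounded in $[-1, 1]$ with no clipping. With the default scale the
per-subject uplift spans roughly $\pm 0.2$ and averages near zero —
subgroup heterogeneity without an overall arm difference, the regime the
method exists for. `benefit_scale = 0` removes all heterogeneity and is the
null used for calibration checks.

Event times are a stand-in, labelled as such: recurrence times are uniform
on (0, 12] months for failures and successes are administratively censored
at 12. The alternative `"exponential"` mode draws constant-hazard times
inverted to hit each subject's 1-year failure probability exactly, which
makes Cox hazard ratios recoverable and is used for parameter-recovery
tests. Neither mode claims a realistic recurrence-time *shape*; only the
1-year endpoint is calibrated. Missingness is MCAR only. The generator
matches marginal covariate shapes, not the joint distribution of a real
trial population — passing tests demonstrate the machinery recovers planted
structure under these idealized conditions, not that any particular real
cohort would yield the same strata.

## Problem sizes and what the checks show

The replicate-level checks run at sizes chosen to make their Monte-Carlo
error small relative to the effects tested: end-to-end recovery uses 50
replicates of $n = 2000$ (at that size the high-stratum hazard ratio falls
below the low-stratum one in essentially all replicates, median high-stratum
HR ≈ 0.7); null calibration uses 40 replicates of $n = 1500$ with
`benefit_scale = 0` (interaction p uniform by Kolmogorov–Smirnov;
Schoenfeld pass rate ≈ 95% at nominal level). Exhaustive Qini oracle checks
cover every arm/success configuration with distinct scores for $n \le 6$
plus randomized tied-score configurations at $n = 7, 8$.

A single run at the trial's own scale ($n = 497$, 27-ish events per
stratum) is *noisy*: the stratification typically enriches the high stratum
for true benefit, yet the observed within-stratum hazard ratio can still
point the wrong way on an unlucky seed. That is a property of the design
being emulated — one fixed split, no repetition — and the reason the
replicate-level checks, not any single trial-scale run, are the package's
evidence of correctness.

## Known limitations

* The `2P(Z=1|X) - 1` identity is biased when arms are imbalanced; the
  registration-order splitter deliberately ignores arm (as an
  enrollment-order split of a real trial would), so mild within-split
  imbalance is expected and only rank-based quantities are trusted.
* Qini coefficients are unnormalized by default and not comparable across
  cohorts of different size.
* No cross-validation, bootstrap CIs for the Qini coefficient, or
  covariate-adjusted Cox models; the workflow mirrors a single
  train/validation/test pass with unadjusted within-stratum hazard ratios.
* Uplift trees, two-model and doubly robust learners are out of scope; the
  one-model transformation is the method implemented.
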