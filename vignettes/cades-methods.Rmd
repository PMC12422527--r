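---
title: "Complication-aware dynamic classifier selection: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Complication-aware dynamic classifier selection: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cades)
```

## The problem

Patients with decompensated cirrhosis are readmitted at high rates (roughly
13% within 14 days and 27% within 30 days in multicenter cohorts), and the
clinical heterogeneity of the population — different complication and
comorbidity patterns imply different risk mechanisms — makes a single global
risk model a poor fit for many patients. `cades` implements a dynamic
ensemble selection (DES) approach: instead of one model for everyone, a
*pool* of heterogeneous classifiers is trained on interpretable,
rule-defined patient subgroups, and a *meta-classifier* decides, per
patient, which pool members are competent to predict that patient's
readmission risk.

## The model

### Subgroups as conjunction rules

A patient subgroup is a conjunction of binary diagnosis literals, e.g.
`(peritonitis=TRUE) AND (gastritis=FALSE)`. `mine_rules()` enumerates every
conjunction up to `max_literals` (default 2) over the diagnosis columns and
keeps those covering at least `min_support` rows with at least
`min_per_class` rows of each outcome class. Exhaustive bounded-depth
enumeration was chosen over heuristic rule induction because it is
deterministic, auditable, and carries an exact recovery guarantee: any
generative rule meeting the support bar is found.

`mine_rules()` defaults to at most 80 rules — the pooled figure reported for
this family of models across all training datasets. A *single* fitted model
uses `max_rules = 12` by default: a pooled count of 80 rules accumulated
over ten training datasets (two prediction horizons times five
cross-validation folds) corresponds to roughly 8–16 rules per fitted model,
and a compact pool also gives the competence model a cleaner selection
problem. Both knobs are exposed.

### The classifier pool

Eleven algorithm families are supported (naive Bayes, k-nearest neighbors,
logistic regression, LDA, QDA, random forest, extremely randomized trees,
AdaBoost, and three gradient-boosting configurations: depth-wise exact,
leaf-wise histogram — the growth strategy that defines LightGBM — and
depth-wise histogram with row/column subsampling). AdaBoost is implemented
as SAMME over depth-1 `rpart` stumps; the boosting variants run on
`xgboost`. Each mined rule is paired with a family (`cycle`: one family per
rule round-robin; `cross`: all pairs), and one full-training-set (FULL) base
per family is always appended so that every test instance has a competent
fallback even when it matches no rule.

Each base trains on its rule's coverage after majority-class undersampling
(default on). Undersampling is applied uniformly — including the FULL
bases — because mixing posteriors calibrated to different base rates across
a dynamically selected ensemble degrades the continuous risk score; balanced
training keeps the pool's posteriors on a common scale. Features come from a
global univariate screen (`p < .05`; Mann-Whitney U for continuous,
chi-square/Fisher for binary variables) with an optional per-base random
subspace. The subspace fraction defaults to 1.0 in `cades()`: with the
10–20 predictors that survive screening on cohorts of this shape, a 0.8
subspace measurably weakened bases without adding diversity beyond what
rules and families already provide; lower it for wide data.

### Regions of competence and meta-features

For a query patient \(x_j\), two neighborhoods of the dynamic selection
dataset (DSEL, a stratified 25% split of the training data never seen by the
base classifiers) are formed:

* \(\theta_j\): the \(K\) nearest DSEL rows by Euclidean distance over
  z-scored screened features (defaults `K = 7`);
* \(\theta'_j\): the *balanced diagnosis-space region* — the \(K'/2\)
  nearest positive-outcome and \(K'/2\) nearest negative-outcome DSEL rows
  by Hamming distance over the binary complication/comorbidity indicators
  (default `K' = 10`). The enforced class balance means a base classifier's
  accuracy over \(\theta'_j\) is chance-corrected: a constant classifier
  scores exactly 0.5.

The meta-feature vector for base classifier \(c_i\) and instance \(x_j\) is
\(v_{ij} = (f_1, f_2, f_3, f_4, f_5, f_6)\): per-neighbor correctness over
\(\theta_j\) (\(f_1\), \(K\) bits), the base's posterior for each neighbor's
true class (\(f_2\)), their mean (\(f_3\)), correctness over the \(K_p\)
nearest DSEL rows in output-profile (decision) space (\(f_4\), default
`Kp = 5`), the base's confidence on \(x_j\) itself (\(f_5\)), and accuracy
over \(\theta'_j\) (\(f_6\)). All features live in \([0,1]\) and
\(|v| = 2K + K_p + 3\). The label \(\alpha_{ij}\) is 1 exactly when
\(c_i\) classifies \(x_j\) correctly (posterior \(\ge 0.5\)). When
meta-training on the DSEL itself, instance \(j\) is excluded from its own
regions (leave-one-out) to avoid self-neighbor leakage.

One design point deserves a flag: the \(f_2\) block is sometimes described
as the "extent of consensus" in the region of competence, but the META-DES
lineage this framework builds on defines it as the base's posterior
probability for each neighbor's true class; the package follows the
META-DES definition.

### Selection and prediction

A meta-classifier \(\lambda\) (default logistic regression; naive Bayes and
random forest available, and \(K, K', \lambda\) are natural grid-search
candidates) maps \(v_{ij}\) to a competence probability. At prediction time
the selected ensemble is the argmax set of competence scores within
tolerance \(\varepsilon = 10^{-9}\); a single selected base predicts
directly, several are aggregated by majority vote (a vote tie resolves
toward the class with the larger mean posterior, then toward the positive
class). The continuous risk score used for AUROC is the mean positive-class
posterior over the selection — the minimal choice consistent with the
selection rule.

### Thresholding and evaluation

Because readmission is rare, accuracy is computed at a sensitivity-
constrained threshold: the largest score threshold whose sensitivity
strictly exceeds 0.5, chosen on training-side (DSEL) predictions, never on
the held-out fold. `run_experiment()` wraps stratified 5-fold
cross-validation where imputation donors, screening, rules, pool,
meta-classifier and threshold are all fit per fold on the training portion
only; the eleven single-family FULL baselines are trained on the same
base-training split with the same screened features. Precision, recall and
F1 are support-weighted, which makes weighted recall algebraically equal to
accuracy — matching how subgroup metrics are conventionally reported.
`subgroup_report()` gives per-rule metrics plus the distribution of selected
classifiers, the per-subgroup model-suitability view that motivates the
framework.

## The synthetic cohort generator

No real multicenter EHR data ships with the package; `generate_cohort()`
emulates its structure so that every stage is testable:

* ten binary diagnoses (six complications, four comorbidities) at the
  prevalences of a 3307-patient decompensated-cirrhosis cohort
  (peritonitis 17.6%, hepatic encephalopathy 7.7%, ruptured esophagogastric
  varices 53.9%, ...), independent by default with an optional one-factor
  Gaussian-copula correlation;
* fourteen labs, log-normal for right-skewed analytes (bilirubin, bile
  acids, INR, platelets, ...) and normal otherwise (albumin, sodium, ...),
  including two discharge labs; age and sex as demographics;
* three latent subgroups assigned first-match-wins (peritonitis; ruptured
  esophagogastric varices; default) — a mandatory default subgroup
  guarantees a partition since overlap semantics are otherwise undefined;
* a per-subgroup logistic outcome model on the standardized latent labs and
  diagnosis indicators. The `heterogeneity` knob scales the divergence
  between subgroup coefficient vectors (including sign flips, e.g. albumin
  protective in one subgroup and adverse in another); at 0 all subgroups
  share one model. A common intercept offset is calibrated by root-finding
  so the expected outcome prevalence hits `base_rate_target`
  (0.128 and 0.266 mirror 14- and 30-day readmission rates);
* missing-completely-at-random injection per column (5% on labs by
  default), always after generation, never on the outcome.

What it deliberately does not emulate: longitudinal trajectories,
informative (MNAR) missingness, survival outcomes, coding noise, and
between-hospital shifts. Tests passing on these cohorts therefore establish
the *mechanics* of the pipeline (contracts, determinism, leakage-freedom,
recovery, calibration), not clinical performance on real EHR data.

## Numerical and procedural choices

* **Fisher/chi-square switch**: Fisher exact (two-sided by the
  point-probability method, made explicit because dialects differ) when any
  expected count is below 5 *or any observed cell is zero*; otherwise
  chi-square with Yates correction. Zero observed cells break the
  chi-square approximation even when all expected counts are exactly 5
  (e.g. a perfectly diagonal 10/0/0/10 table), hence the second clause.
  A zero margin short-circuits to Fisher with p = 1.
* **Mann-Whitney U**: exact two-sided p by full enumeration of group
  assignments (valid under ties, two-sided as twice the smaller tail,
  capped at 1) for pooled size at most 12; otherwise the normal
  approximation with tie-corrected variance and no continuity correction.
* **kNN imputation**: Euclidean distance over z-scored continuous columns on
  mutually observed coordinates, rescaled by the fraction observed; missing
  continuous cells take the mean, binary cells the mode (ties to 0), of the
  k = 5 nearest donors observed in that column. Held-out data is imputed
  against training donors only.
* **MELD**: `9.57 ln(creatinine) + 3.78 ln(bilirubin) + 11.20 ln(INR) +
  6.43`, inputs floored at 1.0 (UNOS convention) so normal-range values
  cannot contribute negative terms; the floor is switchable.
* **Ties and determinism**: all neighbor ties break toward the lower row
  index; every stochastic step (generation, splits, undersampling, feature
  subspaces, tree ensembles) derives its seed from the caller's seed, so
  fits, predictions and reports are bitwise reproducible.
* **Degenerate inputs**: constant columns screen to p = 1; rule subsets
  with a single outcome class (or families unfittable on them, e.g. QDA
  under within-class-constant features) are skipped with a warning; an
  all-skipped pool is an error; an empty rule list leaves a FULL-only pool.

## Problem sizes used by the test suite and experiments

Descriptive, oracle-equivalence, degeneracy and balance checks run on
cohorts of 300–500 rows in seconds. The statistical-oracle checks enumerate
all 2x2 tables with total at most 20 and rank problems up to pooled size 12.
The comparative experiment uses cohorts of n = 4000 (10 seeds, stratified
75/25 holdout); the no-signal calibration uses n = 20000 cohorts with AUROC
measured on 2000 held-out rows — large enough that the chance-level interval
[0.45, 0.55] is insensitive to the evaluation subsample.

## Known limitations

* On these synthetic cohorts the framework does **not** dominate the best
  single-family baseline in AUROC: subgroup membership is fully observable
  from one or two binary columns, so global tree ensembles (extra trees in
  particular) learn the subgroup-specific effects directly, while dynamic
  selection pays for its DSEL holdout, subset undersampling, and hard
  per-instance selection, whose cross-base risk scores mix imperfectly
  comparable posteriors. Measured over 10 seeds at n = 4000 the framework
  trails the best baseline's mean AUROC by about 0.02–0.03. The
  framework's value on such data shows instead in the per-subgroup
  suitability reporting and the oracle-coverage headroom of the pool. On
  real EHR data — where the published results were obtained — fragmented,
  noisy signal is precisely the regime dynamic selection targets; that
  claim is not reproducible without the original data.
* Competence scores from a continuous meta-classifier make exact ties
  vanishingly rare, so the majority-vote branch fires only within the
  \(\varepsilon\)-band; widening \(\varepsilon\) to 0.1 changed AUROC by
  less than 0.01 in our experiments.
* Base probabilities are not calibrated (out of scope); risk scores are
  rankings, not event probabilities.
* Multiclass outcomes, soft/weighted DES variants, and online updating are
  out of scope.

## A worked example

```{r example, eval = FALSE}
cfg <- default_cohort_config(2000, base_rate_target = 0.266, seed = 7)
cohort <- inject_missingness(generate_cohort(cfg), cfg$missingness_rates,
                             seed = 8)
fit <- cades(cohort, seed = 1)
print(fit)

newpat <- generate_cohort(default_cohort_config(500, 0.266, seed = 9))
head(predict(fit, newpat))
subgroup_report(fit, newpat,
                threshold = sensitivity_threshold(
                  predict(fit, fit$dsel, type = "risk"),
                  outcome_values(fit$dsel)))$metrics
```
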