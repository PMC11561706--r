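---
title: "Methods: dataset shift and epistemic uncertainty in aging clocks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dataset shift and epistemic uncertainty in aging clocks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clockshift)
```

## The problem

An epigenetic aging clock is a regression from CpG methylation beta values
(the fraction of methylated reads at a site, in $[0,1]$) to age. Its output
is routinely over-interpreted: the deviation $\Delta$ of the predicted age
from the chronological age $C$ is read as a biological age $B = C + \Delta$,
and a negative $\Delta$ on reprogrammed or embryonic samples is read as
rejuvenation. That reading silently assumes the query samples come from the
distribution the clock was trained on. Reprogramming time courses, other
strains, and other platforms violate that assumption, and a penalized
linear clock has no way to say so — it returns a confident-looking number
for any input.

clockshift implements four complementary diagnostics for this failure mode:

1. **Covariate-shift detection** — per-CpG two-sample Kolmogorov–Smirnov
   tests with Benjamini–Hochberg correction, plus a PCA embedding of the
   merged pair.
2. **Model-family comparison** — the same training data fit by different
   regressor families; disagreement between their rejuvenation estimates
   is model-choice uncertainty made visible.
3. **The Inverse Train-Test Procedure (ITTP)** — can the query dataset,
   labeled with the clock's own predictions, be used to train a model
   that recovers the original training ages?
4. **A Gaussian-process clock** — closed-form posterior variance per
   prediction, which grows as a query point leaves the training cloud.

Because the real inputs of interest are controlled-access-scale GEO
cohorts, the package ships a synthetic-data module that emulates their
statistical structure; every stage of the framework is exercised and
tested on it.

## The synthetic-data generator

`simulate_aging_methylation()` draws ages uniformly on `age_range`
(default 20–80 years) and gives each of `n_age_cpgs` age-linked CpGs a
linear response
$\beta_{ij} = b_{0j} + s_j \cdot \mathrm{age}_i + \varepsilon_{ij}$,
$\varepsilon \sim N(0, \texttt{noise\_sd}^2)$, clipped to $[0,1]$. Slopes
are drawn from `slope_range` (default 0.002–0.008 per year, random sign),
which at the default age span yields per-CpG age correlations of roughly
0.75–0.98 — the upper range of what published clock CpGs show. Baselines
are placed so the noiseless line stays inside the unit interval; clipping
therefore acts only on noise excursions. Remaining CpGs fluctuate around
random baselines with the same noise. The per-CpG geometry (slopes,
baselines) is a deterministic function of the configuration, drawn under
a dedicated sub-seed: two generators given the same base configuration
describe the *same* population, which is what lets a reprogramming course
start from the very process an aging cohort was drawn from.

Design choices worth stating:

* **Clipping, not logit transformation.** The generator stays on the beta
  scale and exercises boundary behavior (saturated columns, censored
  distributions), which downstream code must tolerate.
* **Uniform ages.** The simplest structure satisfying the clocks'
  assumptions; no age stratification.
* **True age-CpG identities are recorded** in the dataset (`age_cpgs`).
  Real data cannot know this; the field exists purely to enable
  support-recovery and selection tests and is documented as
  synthetic-only.

`apply_covariate_shift()` adds a constant or random per-CpG offset to a
chosen fraction of columns (clipped), optionally biasing ages — the
covariate- and response-shift mechanisms in their simplest form. A
zero-offset spec is a bitwise identity.

`simulate_reprogramming_course()` models induced reprogramming as drift
of each CpG toward its nearer extreme of $\{0,1\}$ at
`drift_per_day` $\times$ day, from a day-0 state equal to the base aging
process at a fixed donor age. Age-linked CpGs drift faster by
`age_drift_multiplier` (default 2): the erasure of age-associated marks
during the maturation phase precedes the full loss of somatic identity,
so the age signal disappears from the methylome before the bulk
remodeling completes. Setting the multiplier to 1 gives uniform drift.
This construction matters for the ITTP: under *uniform* moderate drift
the course retains the age-coding geometry of the CpGs, and a model
trained on course features plus predicted ages can still partially
recover the training ages (the behavior real in vivo reprogramming data
shows); only when the age marks are erased does the reciprocal
prediction collapse (the in vitro behavior). The generator can produce
both regimes.

`simulate_anthropometric_cohorts()` builds the low-dimensional
demonstration: ages uniform over 0–276 months, (height, weight) jointly
normal per age with correlation 0.7, 1000 samples per cohort by default.
The shifted cohort's height means saturate ~40 cm lower with near-normal
weight — a stylized short-stature phenotype. Growth curves are smooth
saturating-exponential (height) and linear (weight) means with
age-growing standard deviations; they are invented curves chosen for
realism of scale, not fits to any published table.

What the generator does **not** emulate: array/RRBS platform structure,
probe-level artifacts, cell-composition confounding, sex chromosomes,
age-stratified sampling, or nonlinear age trajectories. Passing tests on
synthetic data therefore demonstrate the *mechanics* of the diagnostics
(calibration, power against the modeled shift classes, closed-form
correctness), not their sensitivity on any particular real cohort.

## Shift diagnostics

The tested CpG set defaults to the clock-relevant subset — in practice
the `top_k` CpGs by absolute Pearson correlation with age
(`select_age_correlated_cpgs()`, ties broken lexicographically by id) —
because shift on the clock's own inputs is what corrupts predictions;
whole-matrix testing is available by passing all CpG ids. Each CpG gets a
two-sided two-sample KS test (`stats::ks.test`; exact p-values where the
sample sizes permit and there are no ties), BH adjustment across the
tested set, and a flag at adjusted $p < q$ with $q = 0.01$. The rejected
fraction is reported with a Wilson 95% interval — an extension over a
bare percentage, clearly labeled as such. PCA uses column-mean centering
without variance scaling, since beta values share one scale.

Null calibration is defined against the only null the generator admits:
one simulated cohort randomly halved. Under that null the rejected
fraction stays below 2% at $q = 0.01$ (empirically it is almost always
exactly 0, as BH under a full null rarely rejects anything); a 0.3
offset on all CpGs at $n = 50+50$ rejects $\ge 95\%$.

## Clocks and the ITTP

`fit_lasso_clock()` is a cross-validated L1-penalized regression
(glmnet): 5-fold CV minimizing mean squared error over an automatic grid
of 100 log-spaced penalties spanning three decades below the smallest
support-emptying value, refit on all data at the chosen penalty, no
feature standardization (shared scale). The fitted object is a sparse
coefficient table plus intercept; `apply_clock()` is the plain dot
product and refuses to run when support CpGs are missing rather than
imputing.

One honest caveat established by the tests: at the reference conditions
(200 samples, 50 informative CpGs, noise 0.03) the CV-optimal clock
predicts held-out ages with $R^2 > 0.99$ but keeps only ~60–80% of the
true informative sites, swapping the rest for correlated decoys. Support
recovery and prediction are different goals; with strongly redundant
age signals the prediction-optimal penalty has no reason to keep every
informative column. Users who care about the identity of selected CpGs
should treat the support as one of many near-equivalent solutions.

The ITTP asks a sharper question than goodness of fit. Case 1 (both
datasets labeled): train model 1 on the training set, score it on the
test set; then train model 2 — same family, same tuning protocol — on
the test features paired with model 1's *predictions* (kept at full
floating precision), and score model 2 against the original training
ages. Both steps above the $R^2 > 0.25$ threshold: interchangeable. Only
step 2: one-way (the test set still contains the information needed to
predict the training set). Case 2 (query unlabeled) uses step 2 alone.
Constant intermediary predictions short-circuit to not-interchangeable
with an explicit reason. The verdict is recomputable from the recorded
metrics alone, and both fits are seeded.

The model-family comparison runs pluggable regressor contracts
(`fit`/`predict` pairs). Lasso and k-nearest-neighbors ship built in,
each tuned by its own grid-search CV; random forests, SVR or boosting
plug in through the same contract rather than being wrapped here.

## The Gaussian-process clock

The GP prior treats the centered ages as
$y \sim N(0, \Sigma + \sigma^2 I)$ with the RBF kernel
$k(x_i, x_j) = s^2 \exp(-\lVert x_i - x_j\rVert^2 / 2\ell^2)$ and white
noise $\sigma^2$. For a query $x_*$ the posterior is closed-form:

$$\mu_* = k_*^\top (\Sigma + \sigma^2 I)^{-1} y, \qquad
  \sigma_*^2 = k(x_*, x_*) - k_*^\top (\Sigma + \sigma^2 I)^{-1} k_*.$$

The reported interval is $\mu \pm 2\sigma_*$ — a credible interval of
two posterior standard deviations. Far from the training cloud
$k_* \to 0$, so $\mu_* \to$ the training mean and
$\sigma_*^2 \to s^2$: the signal variance is the model's uncertainty
ceiling for out-of-distribution queries, and reaching it is itself a
diagnostic ("this sample is nowhere near my training data").

Numerical choices:

* Zero-mean convention realized by centering ages on the training mean
  and adding it back (ages are positive; a raw zero-mean prior would
  bias predictions toward zero).
* Predictive variance is latent-only, matching the posterior form above
  and the $s^2$ ceiling; `include_noise = TRUE` adds $\sigma^2$ for
  observation-level intervals.
* No feature scaling before the kernel: beta values share $[0,1]$.
* Training maximizes the log marginal likelihood by L-BFGS-B in
  log-parameter space within bounds $s^2 \in [10^{-2}, 10^5]$,
  $\ell \in [10^{-2}, 10^3]$, $\sigma^2 \in [10^{-4}, 10^4]$, from a
  heuristic start ($s^2 = \mathrm{var}(y)$, $\ell =$ median pairwise
  distance, $\sigma^2 = 0.1\,\mathrm{var}(y)$), a pure-noise start
  ($s^2$ at its lower bound, $\sigma^2 = \mathrm{var}(y)$), and five
  seeded log-uniform restarts by default.
* A length scale at its lower bound makes the RBF kernel numerically
  indistinguishable from white noise, so pure-noise targets create a
  flat likelihood ridge between the two explanations; among optima tied
  within $10^{-4}$ log-likelihood units the larger-$\sigma^2$
  (noise) explanation is preferred. This is a documented tie-break, not
  a prior.
* Cholesky factorization with diagonal jitter starting at $10^{-10}$
  and escalating tenfold to at most $10^{-6}$ before reporting failure;
  negative predictive variances from roundoff are clamped to zero and
  counted.

Parameter recovery was checked by simulation: data drawn from a known GP
($s^2 = 4$, $\ell = 0.5$, $\sigma^2 = 0.1$, $n = 200$, two features)
returns all three hyperparameters within a factor of two across seeds.

## Group significance tests

GP predictions carry per-sample variances, so group comparisons weight
by them. `z_test_two_predictions()` is the two-prediction normal test.
`meta_regression_groups()` is a random-effects meta-regression of the
predicted ages on an intercept plus a binary group indicator with
per-observation variances $v_i + \tau^2$; $\tau^2$ is estimated by REML
via Fisher scoring with projection onto $\tau^2 \ge 0$ (converged when
the step falls below $10^{-8}$, at most 100 iterations), and inference
on the indicator is a two-sided Wald z-test. The Knapp–Hartung-style
small-sample correction is deliberately not the default, mirroring the
referenced tooling; with one observation per group the model is
saturated and the function falls back to the z-test with a warning. The
design matrix is intercept + indicator — the standard reading of a
two-group moderator. Per-sample rows are used rather than per-group
aggregates by default (`aggregate = TRUE` collapses each group to its
mean with the variance of the mean). Monte-Carlo calibration at
$n = 10 + 10$ under the null gives a type-I rate of about 0.04 at
$\alpha = 0.05$. `mann_whitney()` wraps the exact/normal-approximation
rank test for point-estimate clocks without variances.

## The pipeline

`run_framework()` executes CpG intersection, shift diagnostics, clock
comparison on an internal train/test split, the ITTP (case chosen by
query-age availability), GP predictions with intervals on the selected
CpG subset, and meta-regression between the first and last query groups
(or configured pairs). One global seed fans out to per-stage seeds by
hashing the stage name, so stages are reproducible in isolation. A
failed stage is recorded with its message and its dependents are
skipped; reports contain no timestamps and serialize byte-identically
for a fixed config. Configurations can live in YAML files mirroring the
`framework_config()` arguments.

## Problem sizes

The test suite and the acceptance script run entirely on synthetic data
at deliberate desk scale: cohorts of 100–200 samples with 300–1000 CpGs
for shift/ITTP/clock checks, GP fits at $n \le 200$ with 2–50 features,
2000 Monte-Carlo replicates for test calibration, and 20 seeds for the
KS null. These sizes were chosen so the full suite completes in about a
minute while leaving every statistical conclusion comfortably away from
its threshold.

## Known limitations

* All calibration statements are relative to the generator's modeled
  shift classes (constant/random offsets, extreme-drift courses); a real
  batch effect need not look like either.
* The KS test is per-CpG and marginal; correlated shifts that preserve
  marginals are invisible to it (the PCA view partially compensates).
* The GP clock is exact and therefore $O(n^3)$ in training samples; it
  is intended for cohort-scale ($n$ in the hundreds) training sets, not
  biobank scale.
* The RBF kernel fixes *how fast* uncertainty grows off-distribution;
  other kernels would give other growth profiles, and the ceiling
  argument applies only to stationary kernels with finite signal
  variance.
* Nonlinear age transforms used by some published clocks are out of
  scope; coefficient tables are applied linearly.
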