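# clockshift

Dataset-shift diagnostics and uncertainty-aware epigenetic aging clocks.

Epigenetic aging clocks regress age on CpG methylation beta values and
are widely used to score "rejuvenation" in cellular reprogramming,
embryogenesis, and intervention studies. The number they return is only
meaningful if the query samples resemble the clock's training
distribution — and reprogrammed or embryo-like methylomes usually do
not. clockshift is a toolkit for deciding, before believing a clock,
whether it can be trusted on a new cohort. It is aimed at computational
biologists who train or apply methylation clocks and want the
epistemic-uncertainty side of the analysis to be explicit.

The package implements four complementary diagnostics around one data
container (`methylation_dataset`, a samples × CpGs beta matrix with
per-sample ages/labels):

1. **Covariate-shift detection** — per-CpG two-sided two-sample
   Kolmogorov–Smirnov tests with Benjamini–Hochberg correction
   (`ks_shift_test`, flagged at adjusted *p* < 0.01), plus a PCA
   embedding of the merged pair (`pca_embed`).
2. **Model-family comparison** (`compare_model_families`) — the same
   training set fit by pluggable regressor families; the spread of
   their rejuvenation deltas is model-choice uncertainty.
3. **Inverse Train-Test Procedure** (`ittp_case1`, `ittp_case2`) —
   train model 2 on the query features labeled with model 1's own
   predictions and ask whether it recovers the original training ages;
   verdicts at the R² > 0.25 threshold.
4. **A Gaussian-process clock** (`fit_gpr`, `predict_gpr`) — RBF +
   white-noise kernel, exact log-marginal-likelihood training, and the
   closed-form posterior

   μ\* = k\*ᵀ(Σ + σ²I)⁻¹y,  (σ\*)² = k(x\*,x\*) − k\*ᵀ(Σ + σ²I)⁻¹k\*,

   reported as μ ± 2σ credible intervals. Far from the training cloud
   the variance saturates at the signal variance s² — an explicit
   out-of-distribution alarm. Group effects are then tested with a
   variance-aware REML meta-regression (`meta_regression_groups`), a
   z-test, or Mann–Whitney.

A synthetic-data module (`simulate_aging_methylation`,
`simulate_reprogramming_course`, `apply_covariate_shift`,
`simulate_anthropometric_cohorts`) emulates aging cohorts, covariate- and
response-shifted cohorts, and reprogramming time courses, so the whole
framework runs and is tested without any external downloads.

## Worked example

Train a clock on a synthetic aging cohort, then interrogate a
reprogramming-like time course with every diagnostic:

```r
library(clockshift)

cohort <- simulate_aging_methylation(
  simulation_config(n_samples = 160, n_cpgs = 400, n_age_cpgs = 40,
                    noise_sd = 0.03, seed = 42))
split <- split_train_test(cohort, test_frac = 0.3, seed = 42)

clock <- fit_lasso_clock(split$train, seed = 42)
regression_metrics(split$test$age, apply_clock(clock, split$test)$mu)
#> <regression_metrics> n=48  MAE=0.710  MedAE=0.469  R2=0.996  r=0.998
```

An accurate clock — on its own distribution. Now a reprogramming course
whose age marks are erased during maturation:

```r
course <- simulate_reprogramming_course(
  simulation_config(30, 400, 40, noise_sd = 0.03, seed = 42),
  days = c(0, 10, 20, 28), drift_per_day = 0.02,
  age_drift_multiplier = 3, seed = 43)
cpgs <- select_age_correlated_cpgs(split$train, 40)

ks_shift_test(split$train, course, cpgs = cpgs)
#> <shift_report> 40 CpGs tested (n = 112 vs 120)
#>   rejected at q = 0.01: 100.0% [Wilson 95%: 91.2%, 100.0%]

ittp_case2(split$train, course, seed = 42)
#> <ittp_report> case 2, verdict: not_interchangeable (R2 threshold 0.25)
#>   step 2: R2=-0.010 MAE=15.930
```

Every clock CpG is distribution-shifted, and the course cannot be used
to predict normal aging back. The GP clock quantifies the same warning
per sample:

```r
gp <- fit_gpr(subset_cpgs(split$train, cpgs), restarts = 3, seed = 42)
preds <- predict_gpr(gp, subset_cpgs(course, cpgs))
aggregate(cbind(mu, width = upper - lower) ~ group, preds, mean)
#>   group       mu     width
#> 1     0 49.92935  2.150366
#> 2    10 48.13511 29.955928
#> 3    20 48.13511 29.955928
#> 4    28 48.13511 29.955928

meta_regression_groups(preds[preds$group == "0", ],
                       preds[preds$group == "28", ])
#> <group_comparison> method=meta_reml  effect=-1.814  se=1.388
#>   statistic=-1.307  p=0.1912  tau2=0.708
```

Day-0 samples (drawn from the training process) get ±1-year credible
intervals; once reprogramming erases the age marks the intervals widen
~14-fold. The mean predicted age does drop by 1.8 years between day 0
and day 28, but weighted by the per-sample variances the effect is not
significant (p = 0.19): with this much epistemic uncertainty, the
apparent rejuvenation is not evidence.

The methods vignette
(`vignettes/uncertainty-aware-aging-clocks.Rmd`) documents the models,
parameter choices, and numerical details; `inst/cli/clockshift.R`
exposes the same operations as shell subcommands
(`simulate`, `shift`, `ittp`, `gpr`, `compare`, `run`, `demo-toy`).

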