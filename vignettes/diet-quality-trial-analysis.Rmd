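---
title: "Analysing diet quality in longitudinal randomized trials"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analysing diet quality in longitudinal randomized trials}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dietquality)
```

## The analysis problem

Behavioural nutrition trials in youth with type 1 diabetes (and in many
other populations) assess dietary intake with short multi-day food records
collected repeatedly over follow-up — here, 3-day records at six visits
across 18 months, with HbA1c drawn every 3 months. Two summary outcomes
drive the analysis:

* **HEI2005**, the Healthy Eating Index 2005: twelve density-based
  component scores (nine *adequacy* components that rise with intake of
  fruit, vegetables, grains, milk, meat/beans and oils; three *moderation*
  components that fall with saturated fat, sodium, and energy from solid
  fats, alcohol and added sugars), summing to a 0–100 total. All
  components are scored per 1000 kcal, so the index measures diet
  *quality* independent of energy needs.
* **WPFD**, Whole Plant Food Density: cup/ounce equivalents of whole
  grains, whole fruit, vegetables, legumes, nuts and seeds per 1000 kcal.

Three statistical features make the pipeline non-standard and are the
reason this package exists:

1. **Population-ratio estimation.** Short records estimate an
   individual's usual intake poorly, and the mean of individual
   food/energy ratios is a biased estimate of the group-level density.
   The group mean density is therefore estimated as the ratio of *summed*
   food intake to *summed* energy over all subjects in an arm at a visit
   (`population_ratio()`), which equals the energy-weighted mean of
   individual densities. The same principle is applied to a whole index:
   `hei_population_summary()` pools intake totals over the group and
   scores the pooled densities once (score-of-ratio, not mean-of-scores),
   so each component inherits the ratio-of-totals contract.
2. **A global permutation test.** The treatment comparison is not
   visit-by-visit. Each arm is summarised by its vector of visit-specific
   population ratios, the test statistic is the Euclidean distance between
   the two vectors, and its null distribution is generated by permuting
   subjects' arm labels (each subject carries all of its visits). The
   p-value is the proportion of permuted distances at least as large as
   the observed one.
3. **Intent-to-treat via multiple imputation.** Withdrawal is handled by
   multiply imputing missing outcome visits, analysing each completed
   dataset, and combining results.

## Estimation and uncertainty

`estimate_visits()` reports the population-ratio estimate per (outcome,
arm, visit) with a bootstrap standard error. The resampling unit is the
subject; subjects are resampled with replacement within an arm *jointly
across visits*, preserving within-subject correlation — the package treats
this as an explicit assumption, since resampling independently per visit
would also be defensible. Subjects missing a visit contribute nothing to
that visit's estimate (complete-case at the estimation layer; missingness
is the imputation layer's job). The default of 5000 resamples is
configurable; the tests scale it down for speed.

## The permutation test

`permutation_test()` permutes arm labels over the combined sample,
unstratified: the exchangeability argument rests on randomization of the
whole sample, and the randomization strata are deliberately not preserved
in the null. Ties count as extreme, and the observed labelling is not
added to the permutation set, so `p = 0` is possible at finite permutation
counts (and is clamped downstream when p-values are combined). The
distance is one-sided by construction — larger distance means more
between-arm separation in any direction — so no two-sided correction
applies. With all subjects observed at all visits the statistic is
computed for all permutations by indicator-matrix multiplication, which
keeps 1000-replicate calibration studies inside a coffee break.

Monte-Carlo agreement with exhaustive enumeration is tested on all
datasets small enough to enumerate (up to 8 subjects), and the test's
empirical size under the package's own null generator is required to sit
in [0.03, 0.07] at a nominal 0.05.

## Multiple imputation and pooling

`impute_missing()` implements sequential regression with
predictive-mean-matching donors. Visits are processed chronologically; a
missing subject-visit outcome is predicted from arm, the previous visit
and baseline (with a proper Bayesian draw of the regression coefficients
per imputation), and filled by copying the *entire record* of one of the
five observed subjects with the closest predicted values. Copying whole
records keeps imputed food and energy totals internally consistent, which
matters because every downstream statistic is a ratio of totals. Observed
values are never altered; with no missing data the `m` completed datasets
are identical copies.

Per-imputation permutation p-values are combined with the probit rule
(mean of the probit-transformed p-values mapped back through the normal
CDF), which is idempotent on constants and monotone; the final-visit arm
difference is pooled by Rubin's rules (total variance = within +
(1 + 1/m) × between, t reference with the standard MI degrees of
freedom). The ordering — impute first, then permute each completed
dataset, then combine — and the probit combiner are the package's own
choices; reasonable alternatives (median p, single-imputation stacking)
exist and the combiner is deliberately isolated in
`combine_permutation_p()`.

## Power

`power_two_sample_t()` is the exact noncentral-t power of the two-sided
pooled-variance two-sample t-test; `power_by_simulation()` is its
Monte-Carlo cross-check. Power at an "achieved" sample size uses the
actual 66/70 split; the balanced 68/68 differs by less than 0.001.

## The synthetic-trial generator

No subject-level data accompany the study design this package targets, so
the generator (`simulate_trial()`) is first-class, tested code: every
downstream claim is validated against data with known truth.

* **Design**: 136 subjects by default, stratified permuted-block
  randomization (blocks of 4) over the eight age (<13 / ≥13 years) ×
  HbA1c (<8.5 / ≥8.5%) × regimen (injection / pump) strata, diet visits
  at months 0, 3, 6, 9, 12, 18 with three record-days each, HbA1c every
  3 months. Block size 4 is a design choice — common practice for
  three-factor stratification at this enrolment; the stratum sampling
  probabilities (0.5 / 0.66 / 0.31) reproduce the published baseline
  table's age, HbA1c and regimen distributions.
* **Intake model**: each subject draws a mean density per food group from
  a Gamma distribution with the profile's mean and between-subject SD
  (non-negative without truncation, so additive intervention shifts move
  the group mean exactly); a day's amount is that density times the day's
  lognormal energy plus additive Gaussian day noise truncated at zero.
  The day-noise SD is proportional to the day's expected amount
  (normalised to `density_day_sd` at typical intake): a constant-SD
  version truncates asymmetrically near zero and biases recovered
  treatment effects by up to ~0.1 equivalents/1000 kcal, while the
  proportional version keeps the generator unbiased and matches the
  episodic character of rarely-consumed foods.
* **Calibration**: baseline density means follow the published baseline
  table (whole grains 0.69 oz-eq, vegetables 0.53 cup-eq, whole fruit
  0.28 cup-eq, legumes+nuts 0.17 cup-eq per 1000 kcal; HbA1c 8.1 ± 1.0%;
  energy 1900 ± 450 kcal/day; macronutrient shares 48/16/36), which puts
  the pooled baseline HEI2005 near 57 and baseline WPFD near 1.7. (The
  published baseline WPFD of 1.89 slightly exceeds the sum of its printed
  component rows, 1.67; the generator reproduces the component rows.)
  The study-calibrated profile (`study_effect_profile()`) adds
  intervention shifts ramping from month 3 to a whole-grain-dominated
  full effect at month 18 (WPFD +0.5, HEI2005 ≈ +7) and the published
  withdrawal flow: 11 of 136 subjects, all in the intervention arm,
  leaving 92% retention.
* **Streams**: randomization, intake and missingness use separate seeded
  RNG streams, so changing one facet never perturbs the others, and an
  identical (config, seed) pair reproduces the dataset byte-for-byte.

What passing tests on this generator do **not** show: robustness to
reporting error and energy under-reporting in real food records, to
non-Gamma intake distributions or informative (outcome-dependent)
withdrawal, or to coding differences upstream in the nutrition software
that maps foods to group equivalents. The generator's withdrawal is
missing-at-random given arm and past outcomes by construction.

## Numerical and degenerate-input choices

* Moderation components are scored by piecewise-linear interpolation
  through the published anchors; a density exactly at a threshold scores
  the boundary value.
* Legumes are credited to meat-and-beans (4 oz-eq per cup-eq) only until
  that component's density standard is met; the remainder counts 1:1
  toward total and dark-green/orange vegetables.
* Ratio estimators reject empty groups and non-positive energy;
  `bootstrap_se()` returns 0 with a warning for a single subject.
* Permutation ties are resolved toward significance (≥ with a relative
  1e-12 float guard); permutation p-values of exactly 0 are clamped to
  1/(n_perm+1) before probit combination.
* Problem sizes in the shipped tests are chosen to keep the full suite
  around two minutes: 1000 replicate trials at 999 permutations for size
  calibration, 1000 datasets for the bootstrap-vs-Monte-Carlo comparison,
  five 500-per-arm trials for parameter recovery — each large enough that
  the assertion's Monte-Carlo error is several times smaller than its
  tolerance.

## Worked example

```{r example, eval = FALSE}
trial <- simulate_trial(trial_config(effect = study_effect_profile()), seed = 1)
trial

est <- estimate_visits(trial, outcomes = c("hei2005", "wpfd"),
                       n_boot = 1000, seed = 2)
subset(est, visit_month == 18)

fit <- itt_permutation_test(trial, "wpfd", m = 10, n_perm = 5000, seed = 3)
fit
```

## Limitations

The package consumes already-coded food-group equivalents; it does not
code raw diet records. It implements the population-ratio correction
only — no measurement-error deconvolution of usual-intake distributions —
and no longitudinal mixed-effects models: the inferential machinery is
the permutation test. The HEI2005 standards ship as an editable file, but
later index versions (2010/2015) with different components are out of
scope.
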