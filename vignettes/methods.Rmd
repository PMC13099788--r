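---
title: "Methods: from alcohol intake to advanced colorectal lesions through the gut metagenome"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from alcohol intake to advanced colorectal lesions through the gut metagenome}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(alcomediome)
```

# Scope and model

`alcomediome` implements an epidemiological analysis pipeline for
faecal-immunochemical-test (FIT) positive screening cohorts with
food-frequency-questionnaire (FFQ) dietary data and shotgun metagenomes:

1. **Exposure derivation** — ethanol in g/day is categorised by consumption
   level (0, >0–10, ≥10–20, ≥20 g/day; right-open boundaries), by
   sex-specific guideline adherence (full = 0 g; partial = < 10 g/day for
   women, < 20 g/day for men; non-adherence at or above), converted to
   alcohol units (12 g each) and energy percentage (E%, 7 kcal/g ethanol),
   with sex-specific energy-intake exclusions (<600/800, >3500/4200
   kcal/day for women/men).
2. **Association** — multinomial logistic regression of the three
   colonoscopy groups (controls, non-advanced adenoma, advanced lesions)
   on the exposure plus covariates, with Wald odds ratios, ordinal trend
   tests and sex-interaction Wald tests.
3. **Diversity** — Shannon (`H = -Σ p log p`) and inverse Simpson
   (`D = 1/Σ p²`) with log-linear covariate-adjusted regressions reported
   as percent differences `100(e^β - 1)`; Bray–Curtis dissimilarity, PCoA,
   PERMANOVA with partial Ω², and distance-to-centroid dispersion.
4. **Differential abundance** — per-feature linear models of
   log2-transformed abundances (prevalence ≥ 0.1; normalisation `none`
   for species relative abundances, TSS for pathways; pseudo-counts),
   BH correction per exposure coefficient, and mutual adjustment of
   selected features.
5. **Microbial score** — Gevers-style log-ratio of summed abundances of
   alcohol-elevated vs alcohol-depleted taxa, built under five-fold
   cross-validation so each participant is scored with taxa selected
   without their data.
6. **Mediation** — counterfactual decomposition of the effect of a
   twofold intake increase on advanced lesions into ACME and ADE on the
   risk-difference scale, with nonparametric percentile bootstrap CIs.

A synthetic cohort generator emulates the data structure end-to-end and
carries exact ground-truth mediation effects for recovery testing.

# The mediation estimand and its computation

Exposure is `a = log2(g/day + 1)`; the +1 pseudo-count keeps zero
consumers on the scale (the alternative of dropping them is available via
`log2_alcohol(drop_zero = TRUE)`). The contrast is `a → a + 1`, i.e. a
twofold increase, evaluated at each participant's observed intake and
averaged.

The mediator model is OLS of the score on exposure and covariates
(including the cross-validation fold identity when the CV score is used);
its residual SD defines the counterfactual mediator law
`M(a) ~ N(μ̂(a, C), σ̂)` (homoscedastic normal, the conventional choice).
The outcome model is maximum-likelihood logistic regression on exposure,
mediator and covariates, without exposure–mediator interaction: the
decomposition is then exactly additive (total = ACME + ADE for the
averaged treated/control-referenced variants), matching the additive
decomposition reported in this literature. An interaction flag is
deliberately not implemented.

`decompose()` integrates the potential-outcome probabilities
`Y(a, M(a'))` over the mediator law either by Monte Carlo (`n_sim`
draws; the default for point estimates) or by 21-node Gauss–Hermite
quadrature. The two agree to ~1e-4 on cohorts of this size; quadrature is
used inside bootstrap replicates because it is deterministic and ~100×
faster, which keeps the 300-replicate bootstrap of the recovery tests
inside a CI budget. Proportion mediated is ACME/total and is reported as
`NA` with a flag when the total effect is numerically zero, never ±Inf.

Percentile bootstrap CIs resample participants with replacement and refit
both models per replicate (1000 replicates by default; >10% replicate
failures abort). A quasi-Bayesian alternative (parameter draws from the
asymptotic normals) is available behind `ci_method = "quasi-bayes"` for
cross-checking.

# The cross-validated score and leakage

Within each training set, features pass the prevalence filter, are
log2-transformed, and taxa with BH q < 0.05 are split by direction of
association; a fold whose threshold selects nothing in a direction falls
back to the top `fallback_m` taxa by p-value (flagged). The score is
`log((Σ elevated + pseudo)/(Σ depleted + pseudo))` with one shared
pseudo-count per side — stable for sparse sets; a per-taxon variant is a
flag. Fold assignment is seeded and stratified by outcome.

A subtlety the test suite documents: even with honest cross-validation,
the *pooled* regression of held-out scores on exposure is mildly
anticonservative under the null, because each fold's taxon selection
uses the *other* folds' exposures — scores and exposures are pairwise
but not jointly independent (second-order cross-fitting dependence; it
shrinks with n). The `score_leakage_test()` default therefore tests per
fold — exact by construction, since conditional on the training data the
held-out scores are an independent transformation of the held-out
samples — and combines fold p-values by Bonferroni, which is valid under
arbitrary dependence. The acceptance suite asserts the resulting
near-nominal rejection rate under permuted exposure, and the gross
inflation of the non-CV score under the same null.

# PERMANOVA choices

The tested term's sum of squares is marginal: the drop in Gower-trace
explained variation when the term is removed from the full design (the
`by = "margin"` convention). Significance uses Freedman–Lane permutation
of the reduced-model residual Gower matrix with the design held fixed;
the permutation count (default 999) and seed are required, logged inputs.
The effect size is partial
`Ω² = (SS_term − df·MS_resid)/(SS_total + MS_resid)`, which is centred
near zero under the null (asserted: mean |Ω²| < 0.005 over null
simulations) and can be slightly negative. Negative PCoA eigenvalues from
the semi-metric Bray–Curtis are reported, not corrected; the dispersion
analysis handles them with the usual imaginary-axis correction and
summarises groups by the *median* distance to centroid, tested by
permuting group labels of the distances.

Shannon entropy defaults to natural log (nats); a base flag exists since
conventions differ.

# Differential abundance choices

The default pseudo-count is half the smallest non-zero value of the
(post-normalisation) matrix — the exact pseudo-count used by any given
MaAsLin run is not recoverable, so no test depends on its value beyond
this default. The prevalence boundary is inclusive (a feature in exactly
10% of samples passes at `min_prev = 0.1`). The BH family is the feature
set tested for one exposure coefficient, not pooled across codings or
levels. Mutual adjustment refits each selected feature with the other
selected features as covariates; collinear sets get a ridge-stabilised
fit with a warning rather than a failure.

# What the synthetic generator emulates — and what it does not

Stated-world defaults: ~13% zero consumers overall (women ≈ 2.3× men),
consumer intake lognormal with overall median 9 g/day and sex medians in
ratio 13:5, log-SD 1.3 (backed out of the emulated quartiles 2.2/9/19);
787 species with per-sample richness Normal(88, 15.5) truncated at 1;
five alcohol-elevated and five alcohol-depleted taxa with log-abundance
shift ±0.3 per twofold intake; advanced-lesion prevalence calibrated to
0.28; direct log-odds 0.115 and score log-odds 0.027 per twofold — which
together give a total effect ≈ ln(1.14) per doubling of which ≈12% is
mediated, the world this package is meant to analyse. Covariates are
independent apart from the sex→alcohol shift and mild sex/age outcome
effects, so confounding is mild by default.

Ground truth: because presence and noise draws do not depend on the
alcohol values, regenerating the abundance matrix at doubled intake with
the same seed yields *exact* common-random-number counterfactual scores;
true ACME/ADE are then averages of potential-outcome probabilities over
the simulated covariate distribution. With `gamma_score = 0` the true
ACME is exactly 0; with `beta_direct = 0` the true PM is exactly 1.

Not emulated: inter-taxon correlation beyond compositional closure,
over-dispersed richness beyond the normal model, FFQ measurement error,
FIT haemoglobin, sequencing depth variation, and missing-not-at-random
patterns. A green recovery test therefore establishes correctness of the
estimators under the stated world, not robustness to those features.

# Numerical choices

* Multinomial logit: Newton iterations on the full log-likelihood with
  analytic gradient and observed information, step-halving, ridge
  fallback (1e-8) on a singular information matrix, convergence at max
  |score| < 1e-8; non-convergence and empty outcome categories are
  flagged/errored, never silent.
* Exposure classification is performed on unrounded gram values; the
  boundary tests pin the right-open convention at 10 and 20 g/day.
* Missing continuous covariates (BMI, activity) are set to the cohort
  median; categorical missingness is kept as an explicit `"missing"`
  level, mirroring the adjustment-set footnotes of screening analyses.
* Bray–Curtis uses the Manhattan-distance primitive divided by the
  sample-total sums; a sample with zero total is a named error.

# Worked example

```{r example, eval = FALSE}
cfg <- synth_config(n_participants = 600, seed = 42)
sim <- simulate_study(cfg)
d <- derive_covariates(sim$cohort)
d$l2a <- log2_alcohol(d$alcohol_g_day)
d$score <- sim$score

fit <- fit_multinomial(d, "diagnostic_group", c("l2a", "sex", "age"))
association_table(fit, terms = "l2a", coding = "per_twofold")

res <- mediate(d, "advanced", "l2a", "score",
               covariates = c("sex", "age"), n_boot = 1000, seed = 42)
res
sim$truth$prop_mediated  # generator ground truth for comparison
```

# Known limitations

* The PERMANOVA implementation materialises the n×n Gower and hat
  matrices; fine for cohort-scale n (≤ a few thousand), not for tens of
  thousands of samples.
* `fit_features` assumes homoscedastic Gaussian errors on the log2 scale,
  as the linear MaAsLin family does; count-model families (CPLM, negative
  binomial) and random effects are out of scope.
* The mediation machinery assumes sequential ignorability; no sensitivity
  analysis is provided. Exposure–mediator interaction is intentionally
  unsupported (see above).
* The pooled CV-score association test is mildly anticonservative at
  moderate n (documented above); use the exact per-fold test when the
  test's size matters.
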