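---
title: "Methods: emulating hearing-aid target trials with plasma ADRD biomarker outcomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: emulating hearing-aid target trials}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette records the statistical model behind `biomtte`, the
tunable parameters and their defaults, what the synthetic-data generator
does and does not emulate, and the design decisions taken where the
methodology left genuine choices open.

## 1. The emulated trials

Two point-treatment target trials are emulated in a cohort of
community-dwelling adults aged 70 and over with self-reported hearing
problems, no prior hearing-aid (HA) use, 3MS cognition strictly above
77, and no dementia at time zero. Trial 1 assigns *HA prescription* vs
*none*; trial 2 assigns initiation of a *never* / *rarely-sometimes* /
*often-always* frequency of HA use, with "no prescription or no use"
mapping to *never*. Outcomes are the plasma concentrations of pTau181,
NfL, GFAP (pg/mL) and the amyloid ratio (Aβ42 × 1000)/Aβ40 roughly seven
years later. All contrasts are conditional on surviving to the follow-up
blood draw: imputing biomarker values for the dead is not meaningful, so
the estimand is a survivor-conditional intention-to-treat analogue.

Eligibility with a missing criterion variable is *not* resolved at
screening: such rows are retained and flagged, and the criteria are
re-applied inside every imputed dataset. This mirrors the practice of
reporting a median eligible n across imputations and matters chiefly for
the audiometric sensitivity analysis, where the pure-tone average is
about 91% missing.

## 2. Estimators

**TMLE for mean contrasts.** The outcome is linearly mapped to $[0,1]$
by its observed range $[a, b]$ (no margin). An initial conditional-mean
regression $\bar Q(A, W)$ — a pre-specified linear model by default — is
updated by one logistic fluctuation with offset
$\operatorname{logit} \bar Q$ and clever covariates
$H_a = \mathbb 1(A=a)/g_a(W)$, one per strategy, fitted jointly. The
targeted strategy-specific means are averages of the updated predictions
over all survivors, rescaled to natural units. The fluctuation's score
equations imply $\frac1n\sum_i H_a (Y_i - \bar Q^*) = 0$; the suite
asserts this below $10^{-8}$ on every run. Degenerate predictions are
clipped to $[10^{-4}, 1-10^{-4}]$ before the logit; when the initial fit
respects the outcome range (always true for saturated fits on discrete
data), no clipping occurs and TMLE reproduces plug-in g-computation
*exactly* — the suite's oracle test. With clipping active the
equivalence is approximate at the order of the clipped mass; this is the
one place where the "no margin" scaling and exact-equality ideals meet,
and we kept the no-margin rule.

**Propensity scores and truncation.** Binary trials use logistic
regression; the three-level trial uses one multinomial logistic model
(Newton–Raphson on standardized covariates) so probabilities sum to one
within participant — preferred over separate binary fits for internal
consistency. Inverse-probability weights are bounded by
$\sqrt{n \ln n}/5$; at $n = 2842$ the bound is 30.07, which exceeds 1
and therefore cannot bound probabilities — we read it as a weight bound,
equivalently a propensity floor at its reciprocal. Separation (e.g. from
over-rich product terms) is detected by diverging standardized
coefficients and raised as an error suggesting term removal.

**IPW quantile contrasts.** Per strategy, the weighted type-1 empirical
quantile (smallest observed outcome whose normalized cumulative weight
reaches $\tau$), with weights $1/g_a$, truncated as above; $\tau = 0.9$,
or $0.1$ for the amyloid ratio where low values are adverse. Ties share
cumulative weight. Weights are unstabilized: whether the source analysis
stabilized them is unstated, and truncation already controls the tail.

**Effect modification.** Targeted per-participant predictions under each
strategy are projected by least squares onto a marginal structural model
in strategy, the modifier, and their products. Continuous modifiers
enter through a restricted cubic spline with knots at their
10th/50th/90th percentiles (two basis columns for three knots, linear
beyond the boundary knots); categorical modifiers as indicators. The
initial outcome regression always carries the forced
treatment-by-modifier product — without it the targeted predictions
could not express modification at all. Curves are reported on the
modifier's 2.5th–97.5th percentile span. This
"g-computation-then-projection after targeting" operationalization is
standard; the exact MSM-TMLE algorithm is not pinned down by the source
methodology, which only cites it.

**MARS sensitivity variant.** A compact multivariate-adaptive-
regression-splines fit (forward hinge-pair selection scored by residual
projection, backward pruning by GCV with penalty 3, interactions capped
at degree 2, candidate knots at predictor quantiles) can replace the
GLMs for both nuisance models. The propensity variant selects its basis
by least squares and refits it under a logistic link so fitted values
are proper probabilities. `earth` was not available in the target
environment, so the algorithm is implemented here; it is deliberately
small (default 13 terms) — a sensitivity probe, not a production
learner.

## 3. Missing data

**Chained PMM.** All incomplete variables are imputed by chained
predictive mean matching: per variable, a Bayesian linear regression
draw produces predictions, and each missing cell copies the observed
value of a uniform draw among the `pmm_donor_count = 5` nearest-
predicted donors (the k nearest donors form a contiguous block of the
sorted predictions, which the implementation exploits). Categorical
variables are matched through their numeric codes, so imputed values are
always legal levels. Defaults `n_cycles = 10` donors-5 follow the
de-facto standards of chained-equation software; the methodology names
the method but not these constants. Visit order is ascending missingness
fraction, ties alphabetical. Observed cells are returned bit-identical
and imputed values always lie in the observed support — both asserted
across the suite.

Structural rules: follow-up biomarkers are imputed only among survivors
(the dead are structural missing); hearing-aid frequency is imputed only
where a prescription exists or is itself missing, and is forced to
*never* wherever the (possibly imputed) prescription is 0. Passive
terms — derived quadratic/product columns — are recomputed after every
variable update. The 91%-missing audiometry variable gets a compact
predictor set (demographics, cognition, self-report, treatment) because
its regression rests on a few dozen observed rows.

**Auxiliary selection.** Candidate auxiliary variables plus their
squares and pairwise products are screened by a cross-validated LASSO of
each outcome (folds fixed by seed), keeping nonzero terms at the
**1-SE penalty**; forced treatment-by-modifier products are always
included. We chose `lambda.1se` over `lambda.min` because the module's
contract demands reliable exclusion of null candidates and `lambda.min`
empirically admitted ~40% of pure-noise terms. Which response variable
drives selection is an interpretation: we select against each outcome
and take the union.

**NARFCS delta adjustment.** MNAR sensitivity follows the operational
description: shift constants of 0.05 and 0.25 standard deviations
(negative for the amyloid ratio) are *added to imputed outcome values*
of participants lost to follow-up, after imputation — not the full
not-at-random conditional-model formulation. The SD is the observed-data
follow-up SD per biomarker (observed chosen over imputed-pooled for
determinism). `delta = 0` is an identity.

## 4. Inference

Confidence intervals come from bootstrap-then-imputation: resample
participants with replacement (B = 250), impute M = 2 times *within*
each resample — nesting this way so imputation uncertainty enters the
bootstrap distribution — apply the estimator to each completed dataset,
take the grand mean of all B × M estimates as the point estimate and the
2.5th/97.5th percentiles of the B within-replicate means as the 95%
interval. This is the percentile "MI Boot" pooling; a
Rubin's-rules-within-bootstrap variant was rejected because the B=250 /
M=2 configuration is characteristic of percentile pooling. One set of
imputations serves all analyses: a cache keyed by replicate seed lets
sensitivity analyses consume the primary analysis's imputed datasets,
and whether the source reused resamples across analyses is unstated — we
do, and say so here.

Failed replicates (non-convergence) are dropped and counted; more than
5% failing is an error with diagnostics.

## 5. The synthetic world

The generator emulates the *structure* the analysis assumes, with known
truth:

* ~26% treated, with uptake confounded by age, audiometric and
  self-rated hearing, and cognition (log-odds strength 0.4 by default;
  true propensities stay within [0.02, 0.98]);
* log-scale baseline biomarkers with a fixed 4×4 correlation (positive
  among pTau181/NfL/GFAP, negative with the amyloid ratio), marginals
  loosely matching reported quartiles, and age loadings (+0.15 to +0.25
  SD per SD of age; −0.10 for the amyloid ratio). The age loadings are
  essential: they create the confounding path treatment ← age →
  biomarkers that the double-robustness tests must be able to detect
  when both nuisance models are misspecified;
* follow-up biomarkers as log-scale drift plus persistence (0.6) plus
  lognormal noise, with the treatment effect injected *additively on the
  natural scale among survivors* so the configured mean difference is
  exactly the estimand — making recovery targets analytic;
* ~10.5% death before follow-up, independent of treatment by default (so
  survivor conditioning induces no selection effect; a log-odds flag
  enables treatment-dependent death for stress tests);
* ~55% missing follow-up biomarkers among survivors, MAR given the
  two-wave 3MS auxiliary trajectory and age, with an optional
  `mnar_delta_sd` shift of the missingness score by the latent outcome;
  ~18% missing exposure (MAR on age); 91% missing audiometry,
  independent of everything (emulating a calendar-time mechanism);
* a skin-exam negative-control exposure that is mildly age-related and
  causally null for all outcomes;
* a 10-year dementia indicator driven by the baseline biomarkers, used
  only to train the out-of-sample risk score (the real training sample
  of ~8,329 ineligible participants is inaccessible, so a synthetic
  stand-in cohort is generated for it).

Not emulated: recruitment, randomization to aspirin, calendar/visit
structure beyond the two auxiliary waves, per-biomarker assay-level
missingness (outcome missingness is visit-level), and covariate
missingness outside the hearing/exposure/outcome/auxiliary variables. A
green test therefore establishes that the estimators and the
missing-data machinery do what they claim *under the stated structural
model* — not that the substantive findings of any particular cohort are
reproduced. The biomarker correlation matrix and the baseline-to-
follow-up drift are declared configuration, not inferred from data.

## 6. Numerical choices and degenerate inputs

* Outcome scaling bounds are the per-dataset observed min/max; a
  constant outcome is a degenerate-scaling error.
* Propensity truncation count above 20% of rows is surfaced as a
  diagnostic in the results metadata (not a per-replicate warning).
* Collinear predictors are dropped by rank-revealing QR with a single
  logged warning per imputation; constant-by-design columns (artifacts
  of eligibility subsetting) are dropped silently.
* PMM donor ties and quantile ties are deterministic given the seed;
  weighted quantiles are left-continuous (type 1).
* All seeds derive from one master seed via a fixed integer map, kept
  below 2^31; identical configurations are byte-identical end to end.

## 7. Scaled-down profiles

The `"paper"` profile carries the headline constants (n = 2842, B = 250,
M = 2, 10 imputation cycles, risk-score training n = 8329). The `"ci"`
profile (n = 800, B = 50, 5 cycles) keeps the full suite at desk scale;
the acceptance tests state explicitly where they run scaled-down (e.g.
coverage at B = 100 over 200 cohorts; the negative-control check at
n = 600, B = 50, TMLE contrasts only, over 20 seeds).

## 8. Known limitations

* The pre-specified GLM covariate lists of the source analysis live in
  its supplement; the defaults here (all baseline covariates + risk
  score + the analyzed biomarker's baseline value) are a declared
  stand-in.
* The MSM ribbons in the default profile are not bootstrapped (curves
  are averaged over one full-data imputation pass); bootstrap ribbons
  are available but outside the CI-profile budget.
* No per-protocol/adherence estimands, no longitudinal TMLE, no
  cross-fitting or ensemble nuisance learners — the design is a
  point-treatment emulation throughout.
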