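---
title: "Longitudinal metabolic indices and mortality discrimination in ICU blood-gas series"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Longitudinal metabolic indices and mortality discrimination in ICU blood-gas series}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`icumet` analyzes irregularly sampled arterial blood-gas (ABG) series from
ICU patients with traumatic brain injury. This vignette is the package's
account of the methods: the models and their assumptions, the tunable
parameters and their defaults, what the synthetic cohort generator does and
does not emulate, and the numerical and design choices made where the
underlying methodology leaves room.

## Data model

Time is measured in hours since ICU admission; admission is 0 and every
analysis window (the 6 h admission window, 72 h early horizon, 6 h and 24 h
bins, TUDR periods) is anchored there. A cohort is two tables: a long
measurement table (`patient_id`, `t_hours`, `glucose_mgdl`,
`lactate_mmoll`) and a one-row-per-patient covariate/outcome table.
Validation is total: a table either yields a valid `bg_cohort` or a typed
error. Three deliberate strictness choices:

* **Duplicate timestamps are rejected**, not averaged. Duplicates would
  make trapezoid areas ill-defined; clinical exports occasionally contain
  re-transmitted rows and silently averaging them would hide a data
  problem.
* **Measurements after the recorded ICU discharge are an integrity
  error**, not clipped: the observation span is the denominator of every
  time-weighted quantity, so a record outside it means either the span or
  the record is wrong.
* Rows with both analytes missing are dropped (with a logged count) only
  at the file-reading boundary; a constructed cohort must already be
  clean.

## The index grid

For each marker — glucose (mg/dL), lactate (mmol/L), and the molar
glucose–lactate ratio formed as (glucose/18)/lactate at timestamps where
both analytes coexist in one blood-gas record (no cross-interpolation
between analytes) — the package computes:

* **AB**, the first value at `t <= 6` h. The boundary is inclusive: a
  sample drawn exactly at 6 h still counts as an admission value.
* **MB**, the plain arithmetic mean, kept deliberately: its contrast with
  TWA is itself informative about sampling-intensity bias.
* **TWA**, the trapezoidal area under the piecewise-linear measurement
  curve divided by the observation time. Window boundaries that fall
  strictly inside the sampled span are evaluated by linear interpolation;
  parts of a window outside the sampled span contribute nothing and the
  denominator shrinks to the covered span. The covered-span denominator
  (rather than the nominal window length) avoids biasing the 72 h TWA
  downward for patients whose first sample comes late or whose stay ends
  before 72 h; it also makes the full-stay TWA of a patient sampled only
  to 48 h equal to the 72 h variant, which is the intended semantics of
  "truncated to coverage".
* **CV**, 100·SD/mean with the sample SD (n − 1). The n − 1 denominator is
  the convention of clinical variability work; with the typical dozens to
  hundreds of ABG values per patient the distinction is cosmetic.
* **LC**, lactate clearance 100·(AB − L_h)/AB at horizons 6/24/72 h.
  Positive values mean decline (the clinical "clearance" direction);
  rising lactate gives negative values. Raw mode takes the last
  observation at or before the horizon and requires a second observation
  beyond the admission value; interpolated mode takes the linear
  interpolation between the measurements bracketing the horizon and
  requires a measurement at or after it. When a measurement falls exactly
  at the horizon both modes agree — a tested invariant.
* **TUDR**, the time-unified dysglycemic rate. The stay `[0, icu_los)` is
  partitioned into equal periods anchored at admission; a trailing partial
  period counts when occupied. A period is dysglycemic if *any* glucose
  value in it leaves 70–180 mg/dL; TUDR is the percentage of dysglycemic
  periods among occupied periods. The any-excursion rule (rather than a
  period mean or a time fraction) was chosen because the metric's purpose
  is to count excursion episodes per unit time independent of how often a
  period was sampled; a period mean would re-introduce exactly the
  within-period sampling-intensity dependence the metric removes.

The adaptive period length scans 1, 2, 3, 4, 6, 8, 12 h in ascending order
and selects the first whose **median over patients** of the per-patient
occupied-period fraction reaches 95%. The median is taken over patients
(not pooled over periods) so that a few very long stays cannot dominate
the choice. If no candidate qualifies the largest is used with a warning —
a degenerate-sampling situation that the eligibility rule (≥ 4 ABG/day)
should already have excluded.

All index computations are deterministic; there is no randomness anywhere
in the index module.

## Synthetic cohorts

The generator emulates the *structure* the analysis assumes, so that every
downstream operation can be exercised and checked against known ground
truth:

* **Trajectories.** The mean curve per marker is
  `m(t) = plateau + (baseline − plateau)·exp(−decay·t) + bump(t)` with a
  Gaussian secondary peak for non-survivors. Defaults: survivor lactate
  1.9 → 0.80 mmol/L at 0.040/h; non-survivor lactate 1.9 → 0.85 mmol/L at
  0.035/h plus a 0.40 mmol/L peak centered at 132 h (day 5.5, SD 26 h);
  glucose 145 → 126 (survivors) and 156 → 131 mg/dL with a 16 mg/dL peak
  at 150 h (non-survivors). These shapes reproduce the qualitative matched
  -cohort pattern — near-identical admission lactate, survivor decline to
  a plateau within ~3 days, a biphasic non-survivor course with a days 4–8
  rebound, and a smaller late glucose rise — and the default magnitudes
  were set once so that a simulated cohort of 1000 patients lands near
  the published matched-cohort medians (TWA lactate ≈ 0.88 vs
  1.16 mmol/L) and a TWA-lactate AUC near 0.8.
* **Heterogeneity and outcome.** Patient-level multiplicative log-normal
  jitter (SD 0.25 for lactate, 0.06 for glucose) scales baseline and
  plateau. Mortality is Bernoulli with logit `−2.4 + 1.4 × TWAL_latent`,
  where `TWAL_latent` is the noise-free, continuous-time TWA of the
  patient's *base* (no-peak) lactate trajectory over 240 h, computed in
  closed form. Generating the outcome from the latent TWA makes
  time-weighted lactate the generatively best index — so index-recovery
  and model-power tests are well-posed — and exporting it in the ground
  truth makes logistic parameter recovery an exactly specified problem.
  The secondary peak is added *after* outcome assignment, which is why the
  ground truth carries both the latent and the realized (full-stay,
  peak-included) true TWA.
* **Sampling.** A renewal process with exponential gaps (mean
  24/`sampling_rate` h, truncated at 6 h) starting after a uniform
  0.15–0.6 h admission delay, matching the reported median ~0.25 h first
  -sample delay and the ≥ 4 analyses/day eligibility floor (default 6/day,
  the practical ICU rhythm). Glucose and lactate are observed jointly at
  each time — blood-gas panels report both — so the ratio series is dense.
  Noise is independent Gaussian per analyte with positivity floors
  (20 mg/dL, 0.1 mmol/L).
* **Covariates and stay.** Length of stay is log-normal by group
  (medians 360 h survivors, 215 h non-survivors, truncated to
  76–1000 h); covariates are drawn with outcome-dependent shifts (older,
  higher SAPS II, lower GCS, more hypertension/CKD in non-survivors) so
  unmatched groups are imbalanced the way a matching method expects.

What the generator does **not** emulate: severity-linked (missing-not-at
-random) sampling intensity, treatment feedback (insulin closing the loop
on hyperglycemia), physiologic lactate kinetics beyond the
exponential-plus-peak shape, measurement-device error structure, or
inter-center heterogeneity. Passing tests therefore demonstrate the
statistical machinery is correct under the stated generating process, not
that real TBI cohorts will show any particular effect size.

A fixed `seed` in `sim_config()` makes the generator byte-identical across
runs; determinism is asserted in the tests.

## Matching

Propensity scores come from a maximum-likelihood logistic fit of the
outcome on the eight admission covariates (age, sex, BMI, GCS, isolated
TBI, hypertension, chronic kidney disease, SAPS II); zero-variance
covariates are dropped with a warning and (quasi-)separation is an error.
Matching is greedy 1:2 nearest-neighbor without replacement on the logit
scale with caliper 0.2·SD(logit). Where the underlying procedure is
conventionally underspecified, the package fixes deterministic choices:

* cases are processed in **descending propensity score** (hardest to match
  first), the common nearest-neighbor convention;
* ties in |Δlogit| break by the smaller control id;
* greedy rather than optimal matching, matching the nearest-neighbor
  default of the standard matching tools.

Balance is reported as standardized mean differences before/after
matching — continuous: |Δmean|/√((v₁+v₀)/2); binary:
|Δp|/√((p₁(1−p₁)+p₀(1−p₀))/2) — with a pass flag at 0.10. Caliper
soundness (every matched pair within the caliper, no control reused) is
asserted exhaustively in the tests, and balance improvement is checked
over 100 seeded confounded cohorts.

## Trajectory model

The response is the interval TWA of a marker in fixed-width bins (24 h for
the primary analysis — robust and interpretable — and 6 h for
spline-resolution visualization). The model has fixed effects for group,
spline time and their interaction, a random intercept per patient, AR(1)
residual correlation, and is estimated by REML (ML on request for
likelihood-ratio comparisons of knot counts; the interaction model nests
the main-effects model, so the LR statistic is non-negative — tested).

* **"Five degrees of freedom"** is implemented as a 5-column restricted
  cubic spline basis, i.e. 6 knots at the Harrell quantiles
  {0.05, 0.23, 0.41, 0.59, 0.77, 0.95} of the observed bin midpoints. The
  basis is the truncated-power natural-spline parameterization, scaled by
  (k_K − k₁)²; tail linearity and C² continuity at the knots are verified
  by finite differences.
* **AR(1) is indexed by bin sequence number**, not continuous time gaps:
  the bins are fixed-width by construction, so order-based AR(1) is exact
  for complete panels and the conventional choice for panels with missing
  bins (which are simply absent rows; nothing is imputed).
* **Estimated marginal means** at each ICU day's midpoint are linear
  combinations x'β of the fixed effects with variance x'Vx; daily group
  contrasts use the normal approximation with Bonferroni adjustment over
  the number of days tested (10 by default). Because the model contains no
  covariates besides group and time, the EMM at a time point *is* the
  model-based group mean — on group-constant data it equals the raw group
  means, a tested identity. Days beyond the modeled support produce an
  extrapolation warning.
* The group × time test reported with the fit is the Wald chi-square on
  the five interaction coefficients; its type-I error is verified by
  simulation (400 null seeds, rejection rate within [0.03, 0.08]).

## Outcome models

* **Group tables**: Mann–Whitney U (tie-corrected, two-tailed) for
  continuous indices, Fisher's exact test for categorical covariates.
* **Collinearity screen**: pairwise Spearman ρ; |ρ| > 0.50 flags a pair.
  The time-weighted member is retained; when both members are time
  -weighted (TWA lactate vs TWA ratio — rank correlation near 0.9 by
  construction) both are kept but routed to separate model families,
  which is exactly how the four-model grid arises: {glucose + lactate}
  vs {ratio} × {first 72 h} vs {full stay}, each adjusted for sex and
  SAPS II.
* **Variance estimators**: classical Wald; cluster-robust sandwich at the
  match-set level with HC0 meat and finite-cluster factor G/(G−1) (with
  singleton clusters this is identically the heteroskedasticity-robust
  sandwich — asserted exactly); and conditional logistic regression
  stratified by match set as a sensitivity analysis. OR, 95% CI, z and p
  always come from the same covariance, so p < 0.05 and "CI excludes 1"
  agree by construction.
* **VIF** is the classical design VIF — the diagonal of the inverse
  correlation matrix of the predictor columns — so exactly orthogonal
  predictors give exactly 1; it measures design collinearity rather than
  the IRLS-weighted version.
* **ROC/AUC**: Mann–Whitney identity with half-credit ties, DeLong
  variance/CI, and the paired DeLong test for competing indices (both via
  pROC, cross-checked in the tests against exhaustive pair counting and a
  subject-level bootstrap). All indices are scored for non-survival;
  indices whose higher values predict survival (the ratio family) are
  reported in their natural direction with a flag, never silently
  inverted.
* The univariable screen uses two-tailed α = 0.05 without multiplicity
  correction — screening, not inference; the only formal multiplicity
  adjustment in the pipeline is the Bonferroni on daily contrasts.
* Missingness is handled by complete-case analysis throughout, with
  dropped-row counts logged.

## Pipeline

`run_pipeline()` chains simulate (or load) → indices → match →
trajectories → predict with flat CSV/JSON handoffs so each stage is
independently testable and replaceable; every run directory carries the
configuration, its fingerprint and the seed, and deterministic stages
rerun byte-identically. Stage warnings (TUDR fallback, unmatched cases,
unmatched-analysis caveat) are collected and surfaced by
`render_report()`, which renders a markdown report and tolerates missing
stages.

## Problem sizes and numerical choices

The verification suite uses sizes chosen to make the statistical
assertions sharp while staying desk-scale: 1000 random series for the TWA
oracle (relative tolerance 1e−6 against dense piecewise-linear resampling
with the sample times included in the grid, which makes the oracle exact),
score sets up to 200 subjects for exact AUC pair counting, 100 seeded
cohorts of n = 300 for matching soundness, 300 seeds of n = 400 for
cluster-robust coverage of a generating log-OR of 2.0 (band 93–97%), and
400 seeds of 100 patients × 40 six-hour bins for the trajectory-model
type-I error. Spline smoothness is checked to 1e−4 (second derivative in
the linear tails) and 1e−8 (continuity at knots); boundary conventions are
inclusive at the admission window and half-open `[k·w, (k+1)·w)` for bins
and TUDR periods, with a sample exactly at discharge folded into the
trailing period.

## Known limitations

* Greedy matching can be dominated by optimal matching on adversarial
  propensity configurations; weighting (IPTW), exact-matching layers and
  multiple imputation are out of scope.
* The conditional-logistic sensitivity fit uses the exact stratified
  likelihood and can be slow or fragile under near-separation within
  strata (strong planted effects at small matched n).
* AUC confidence intervals are clipped to [0, 1]; DeLong variance is
  asymptotic and can misbehave at AUC ≈ 1.
* The generator's realism limits are listed above; in particular,
  clinically driven sampling means real TWA indices carry a
  sampling-intensity signal that the renewal-process simulation does not
  reproduce.
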