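# icumet

Longitudinal metabolic indices for ICU mortality analysis after traumatic
brain injury (TBI).

## The problem

After severe TBI, systemic glucose and lactate reflect the evolving
secondary-injury cascade, yet most prognostic models use a single admission
value. Arterial blood-gas (ABG) series from routine ICU care are irregularly
sampled — frequent during crises, sparse when stable — so a plain arithmetic
mean over-weights unstable phases. `icumet` implements the full longitudinal
index methodology for such data and the statistical pipeline that compares
the indices as mortality discriminators in a severity-balanced cohort:

* **Index grid** per patient and marker (glucose in mg/dL, lactate in
  mmol/L, and the molar glucose–lactate ratio, glucose/18 ÷ lactate):
  * admission value **AB** — first value within 6 h of ICU admission;
  * mean **MB** and time-weighted average **TWA** — the trapezoidal area
    under the measurement curve divided by the observation time,
    `TWA = ∫ m(t) dt / T`, over the full stay and the first 72 h;
  * coefficient of variation **CV** = 100·SD/mean; lactate clearance
    **LC** = 100·(AB − L_h)/AB at h ∈ {6, 24, 72}, with the horizon value
    `L_h` read either from the last raw in-window observation (raw-LC) or
    by linear interpolation between the bracketing measurements (ip-LC);
  * time-unified dysglycemic rate **TUDR** — the stay is cut into
    equal-length periods anchored at admission (the shortest of
    1/2/3/4/6/8/12 h giving ≥ 95% median per-patient coverage) and TUDR is
    the percentage of measurement-containing periods with any glucose
    excursion outside 70–180 mg/dL.
* **Severity-balanced cohorts**: eligibility screening (adults, ≥ 72 h stay,
  ≥ 4 ABG/day, no diabetes) and 1:2 nearest-neighbor propensity-score
  matching without replacement, caliper 0.2 SD of the logit propensity
  score, with standardized-mean-difference balance diagnostics (< 0.10
  target, Love-plot-ready output).
* **Trajectory comparison**: linear mixed model on interval-TWA values with
  restricted-cubic-spline time (6 knots, 5 df), group × time interaction,
  random patient intercept and AR(1) within-patient correlation; estimated
  marginal means per ICU day with Bonferroni-adjusted daily contrasts.
* **Discrimination and regression**: Mann–Whitney/Fisher group tables,
  Spearman collinearity screen (|ρ| > 0.50 routes time-weighted indices to
  separate model families), univariable and multivariable logistic models
  with classical, cluster-robust (match-set) or conditional (match-set
  stratified) variance, design VIFs, ROC/AUC with DeLong confidence
  intervals, and paired DeLong tests between competing indices.
* **Synthetic cohorts**: a generator that emulates the data structure the
  analysis assumes — renewal-process sampling ≥ 4/day, admission delay
  0.15–0.6 h, survivor lactate declining to a plateau, non-survivor lactate
  biphasic with a secondary peak around days 4–8, outcome generated from
  the latent (noise-free) time-weighted lactate — with exported ground
  truth for parameter-recovery testing.

## Worked example

```r
library(icumet)

sim <- simulate_cohort(sim_config(n_patients = 200, seed = 42))
idx <- cohort_index_table(sim$cohort)
roc_auc(idx$twal, idx$outcome)
m   <- match_cases(sim$cohort)
rep <- run_model_suite(idx, matched = m)
rep$multivariable$glucose_lactate_full
```

prints (abridged):

```
<bg_cohort> 200 patients, 23413 measurements
  non-survivors: 51 (25.5%)
<roc_result> AUC 0.798 [0.732-0.864] (51 cases / 149 controls)
<matched_cohort> 32 sets (32 cases matched, 19 unmatched)
  caliper: 0.3751 (logit scale)
<logistic_fit> n = 87, variance = cluster_robust
        term  estimate      se       z         p        or
        twal   5.23500 1.25600  4.1690 3.053e-05 1.878e+02
        twag   0.11530 0.03931  2.9320 3.364e-03 1.122e+00
         abg   0.03102 0.02095  1.4810 1.386e-01 1.032e+00
```

Time-weighted average lactate (`twal`) discriminates ICU mortality
(AUC 0.80) and stays independently associated after matching and
adjustment (odds ratio per 1 mmol/L with cluster-robust 95% CI), while the
admission glucose value (`abg`) does not — the qualitative pattern the
index family is designed to expose. The trajectory side:

```r
tab <- interval_twa_table(sim$cohort, "lactate", 24, 10)
fit <- fit_trajectory_model(tab)
emm_daily_contrasts(fit)$contrasts
```

```
<trajectory_fit> RCS(5 df) mixed model, 1821 obs, 200 patients
  random intercept SD 0.229 | AR(1) rho 0.300 | resid SD 0.113
  group x time Wald chi2(5) = 306.12, p = 4.851e-64
  day estimate     se      z p_raw  p_adj
1   1   0.1763 0.0413 4.2676 0e+00 0.0002
2   2   0.1448 0.0400 3.6190 3e-04 0.0030
```

i.e. daily non-survivor minus survivor lactate contrasts with Bonferroni
adjustment over the ten ICU days.

An end-to-end run (`run_pipeline()`) writes all stage outputs (cohort CSVs,
index grid, matched sets, balance, trajectory EMMs, regression/ROC tables)
to a run directory and `render_report()` assembles them into markdown.

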