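# akiread

Acute kidney injury (AKI) episode detection from serial serum creatinine,
and risk modelling of unplanned hospital readmission or death within 90
days of discharge.

`akiread` is aimed at clinical epidemiologists and health-data scientists
working with linked laboratory and hospital-episode data. It implements,
as a tested and reusable pipeline, the full analysis design behind the
question *"is AKI an independent predictor of unplanned readmission, and
does it improve clinical decisions?"*:

* **AKI e-alert engine** — KDIGO-based detection and staging of discrete
  AKI episodes (up to 90 days) from long-format creatinine results, using
  a rolling baseline (median of results 8–90 days back, falling back to
  91–365 days), the 1.5× seven-day-low rule and the 26 µmol/L 48-hour
  rule; prior-episode counting (91–1095 days), the >20% discharge
  non-recovery flag, and CKD-EPI (2009) baseline eGFR.
* **Cohort builder** — index admission selection (first with AKI, else
  last of the study year), the 26 candidate predictors (renal measures,
  admission context, social flags, Quan-mapped Charlson comorbidities),
  composite outcomes at 30/60/90 days, and ICD-10 readmission cause
  groups.
* **Models** — univariable odds ratios, multivariable logistic regression,
  and backward stepwise elimination at p ≥ 0.01 with joint handling of
  term groups (AKI stage trio, age and eGFR linear+quadratic pairs),
  producing the six named predictor-subset models.
* **Validation** — C statistics with DeLong intervals and paired tests,
  calibration slope, (standardised) Hosmer–Lemeshow, and bootstrap
  internal validation with optimism correction and variable inclusion
  frequencies.
* **Decision analysis** — net benefit
  `TP/n − FP/n · t/(1−t)` across thresholds against treat-all /
  treat-none, categorical NRI and IDI with bootstrap intervals.
* **Synthetic cohort generator** — the source cohort is a protected
  regional data linkage, so the package generates synthetic patients
  (creatinine trajectories with injected staged episodes, admission
  histories, comorbidity codes, outcomes from a configurable logistic
  model) carrying ground-truth labels against which every stage is tested.

## Worked example

Detect and stage an episode in a toy series — a stable baseline of ~80
µmol/L, then a rise to 170 (ratio 2.1 → stage 2) resolving by day 104:

```r
library(akiread)
detect_episodes(times  = c(10, 40, 70, 100, 102, 104, 110),
                values = c(78, 82, 80, 170, 130,  96,  80))
#>   start_time end_time peak_stage baseline_used peak_value           trigger
#> 1        100      104          2            80        170 ratio-vs-baseline
```

A univariable odds ratio from published two-by-two counts — AKI stage 3
(150 events / 181 non-events) against the no-AKI reference group
(2154 / 11676):

```r
or <- univariable_odds_ratio(150, 181, 2154, 11676)
sprintf("OR %.2f (%.2f-%.2f)", or$or, or$ci_low, or$ci_high)
#> "OR 4.49 (3.60-5.60)"
```

End to end on a synthetic cohort:

```r
gen    <- generate_cohort(synth_config(n_patients = 4000, seed = 42))
built  <- build_cohort(gen$labs, gen$admissions, gen$deaths, gen$demographics)
models <- predictor_subset_models(built$cohort)
#> Assembled cohort: 3978 patients included, 22 excluded (chronic RRT)
#>   AKI 623 (15.7%); 90-day outcome 750 (18.9%)
```

The apparent C statistics order as expected — richer candidate sets
discriminate better, and AKI alone is informative but weak:

```
full               C = 0.674
best_stepwise      C = 0.665
admin_only         C = 0.632
biochem_plus_age   C = 0.618
age_alone          C = 0.573
aki_alone          C = 0.541
```

Bootstrap internal validation and decision analysis:

```r
boot <- bootstrap_validate(built$cohort, B = 20, seed = 42)
#> apparent C 0.665  optimism 0.011  corrected C 0.654  slope 0.91
scores <- lapply(models[c("best_stepwise", "admin_only", "age_alone", "aki_alone")],
                 predict_risk, rows = built$cohort)
decision_curve(scores, built$cohort$outcome_90)
#> highest mean net benefit in band 0.20-0.40: best_stepwise
categorical_nri(scores$admin_only, scores$best_stepwise,
                built$cohort$outcome_90, c(0.1, 0.3), n_boot = 500, seed = 1)
#> NRI +0.085 (+0.049 to +0.116)
```

Here the detected AKI stages agree with the generator's injected truth for
>99% of patients, the realised event rate (18.9%) sits at the calibrated
target, and adding the renal measures to the administrative model shifts
net benefit and reclassification in the expected direction.

`run_pipeline(pipeline_config(...))` chains all stages and writes a
reportable bundle (cohort, episode and model CSVs, decision-curve TSV,
summary JSON stamped with config hash and seed);
`inst/cli/akiread.R` exposes the same stages as `simulate / detect /
build / fit / validate / dca / all` subcommands.

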