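---
title: "Methods: AKI episode detection and readmission risk modelling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: AKI episode detection and readmission risk modelling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette documents the models and procedures implemented in `akiread`,
the assumptions behind them, the choices made where the methodology was
genuinely open, and what the synthetic-data tests do and do not demonstrate.

## The scientific problem

Acute kidney injury (AKI) — an abrupt rise in serum creatinine relative to a
patient's own baseline — is common in hospitalised patients and detectable
in a standardised way from routine laboratory data alone. `akiread`
implements a complete analysis pipeline for the question of whether AKI
during a hospital admission independently predicts *unplanned readmission or
death within 90 days of discharge*, and whether adding AKI to a prediction
model improves clinical decisions:

1. detect and stage AKI episodes from serial creatinine (e-alert criteria,
   rolling baseline);
2. assemble a discharge cohort with 26 candidate predictors and composite
   outcomes at 30/60/90 days;
3. fit univariable and multivariable logistic models with backward stepwise
   elimination;
4. validate internally by bootstrap with optimism correction;
5. assess clinical utility by decision curve analysis and categorical
   NRI / IDI.

Because the cohort this analysis design comes from is a protected regional
data linkage, the package ships a synthetic cohort generator that emulates
the data structure with known ground truth, so every stage can be tested
quantitatively.

## AKI episode detection

A creatinine result opens an episode when any of three criteria fires:

* value $\ge$ 1.5 $\times$ the **rolling baseline** — the median of all
  results 8–90 days earlier, or 91–365 days earlier if the first window is
  empty (both windows closed at both ends; integer day labels give no
  open/closed notation, so we take the inclusive reading);
* value $\ge$ 1.5 $\times$ the lowest result within the previous 7 days;
* value more than 26 µmol/L above the lowest result within the previous
  48 h.

The short-window lows are computed over results strictly before the current
one. Staging uses the ratio of the value to the baseline identified when the
episode opened: 1.5–1.9 is stage 1, 2.0–2.9 stage 2, $\ge$ 3.0 stage 3; a
value $\ge$ 354 µmol/L is always stage 3; a rise that meets only the
absolute 48-h criterion is stage 1. Episode severity is the highest stage
achieved.

Episodes last at most 90 days. The closure rule is not fully specified by
the e-alert definition beyond the cap, so we fixed one: an episode ends at
the first result at or below 1.2 $\times$ its baseline (the same multiplier
as the non-recovery flag), or 90 days after it started, whichever comes
first. After closure the rolling window re-computes from post-episode data,
so a persistently elevated plateau becomes the *new* baseline — a further
slow rise is then classified as CKD progression/non-recovery rather than
recurrent AKI, and only a fresh acute rise re-qualifies.

Two further bookkeeping rules: *prior* episodes are those starting 91–1095
days before the index episode (or index admission when there is no index
episode), and *non-recovery* means a discharge creatinine strictly more than
20% above baseline. Baseline kidney function is the CKD-EPI (2009) eGFR at
the baseline creatinine; no race coefficient is applied by default (the
source population is a single UK region), but the published 1.159 factor is
available as an argument. Inputs in mg/dL are converted at 88.4 µmol/L per
mg/dL.

One ambiguity is worth flagging rather than silently resolving: results
measured during the index admission but before the first qualifying result
can fall inside the 8–90 day window and therefore enter the baseline. The
implementation includes them; with daily inpatient sampling their influence
on a median over an 83-day window is small.

## Candidate predictors and models

The 26 candidate predictors are encoded as: age and baseline eGFR with
linear plus quadratic terms (centred at 70 years and 60 ml/min/1.73 m² and
scaled per 10 units before squaring — centring improves conditioning and
does not change fitted probabilities); AKI stage as three dummies against
"no AKI"; counts (admissions in the prior year, prior AKI episodes) linear
per unit; length of stay per week; and binary flags for sex, residential
care, deprivation, rurality, emergency/medical-ward/ICU admission,
non-recovery, and the 12 Charlson comorbidity groups (Quan ICD-10 mapping,
flags only, unweighted).

Models are maximum-likelihood logistic regressions. Backward elimination
removes, at each step, the term-group with the largest p-value at or above
the threshold (default $p \ge 0.01$, chosen in the source analysis to
approximate BIC at large n) and refits until all groups are below it.
Groups with several columns — the AKI trio and the two linear+quadratic
pairs — are tested jointly; the analysis this design follows reports a
single inclusion percentage for "baseline eGFR overall", which implies
joint handling, but does not name the test, so we use a likelihood-ratio
test for multi-column groups and the two-sided Wald test for single
columns. Ties are broken by dropping the group whose removal costs the
least log-likelihood, making the elimination trace deterministic.

Six named models are produced: the full model (all candidates, no
selection), the best stepwise model, and stepwise models restricted to
administrative data only, renal biochemistry plus age, age alone, and AKI
alone.

## Performance assessment

Discrimination is the C statistic (Wilcoxon ROC area, ties counted one
half) with a DeLong variance; paired model comparisons use the DeLong test
(the source analysis cites a pairwise comparison without naming the
algorithm; DeLong is the standard choice and the test suite cross-checks it
against a sign-flip permutation oracle and an independent ROC
implementation). Calibration is reported as a decile table and as the
calibration slope — the coefficient from refitting the outcome on the
model's linear predictor, with values below 1 indicating overfitting.

The Hosmer–Lemeshow statistic is computed on risk deciles with $g-2$
degrees of freedom. Because the statistic grows with sample size, a
*standardised* version recomputes it on repeated random subsamples of a
reference size and averages; the exact standardisation formula in the
source analysis is cited but not restated there, so the subsample scheme
here is a documented stand-in, and the raw statistic is always reported
alongside.

Internal validation follows the bootstrap optimism recipe: B resamples
(default 500), the *entire* backward-selection process rerun in each
resample, each bootstrap model scored in its own resample and in the
original data; the mean difference of the two C statistics is the optimism,
subtracted from the apparent C. Calibration slopes of bootstrap models
evaluated in the original data give the corrected slope with a percentile
interval, and per-group inclusion frequencies over resamples quantify
selection stability. Resampling is by patient, with one RNG substream per
resample, so a skipped degenerate resample does not shift the others.

## Decision analysis

Net benefit at threshold probability $t$ is
$\mathrm{TP}/n - (\mathrm{FP}/n) \cdot t/(1-t)$, with a patient classified
positive when their predicted risk is at or above $t$ (the equation needs a
fixed convention; we close the classification at the threshold). Decision
curves compare each model with treat-all and treat-none over a default grid
of 0–0.6 in steps of 0.01, highlighting the pre-specified 0.2–0.4 band.
Categorical NRI uses low/medium/high categories under two cutpoints
(defaults 0.1/0.3 for the main outcome, 0.01/0.1 for the pulmonary-oedema
outcome); a risk exactly at a cutpoint falls in the upper category
(lower-inclusive convention, documented because the boundary membership is
not specified anywhere). NRI and IDI intervals are percentile bootstrap
with 2000 seeded resamples; the interval method is unstated in the source,
so this choice is the package's own.

## The synthetic cohort generator

The generator emulates the structure the analysis assumes, with defaults
fixed at the published cohort composition: 16453 patients, 15.9% with an
index AKI episode (stage mix 65.5/21.9/12.6%), eGFR categories at
59.8/24.4/11.5/4.3%, published comorbidity and admission-context
prevalences, an 18.6% 90-day event rate with 11.8% of events occurring as
death without readmission. Outcomes are Bernoulli draws from a logistic
model whose default coefficients are the published best-stepwise odds
ratios; the intercept is calibrated to the target event rate by
root-finding, and an unreachable target is an explicit error.

Design choices, made once and not revisited:

* **Testing cadence.** Community creatinine tests arrive with exponential
  gaps (mean 60 days) plus daily sampling during every admission. The real
  testing-frequency distribution is not described anywhere we could follow,
  so this cadence is a stated assumption, not an inference. One
  pre-admission test 30–60 days before index is guaranteed, matching the
  complete-baseline-capture property of a single-laboratory population.
* **Baselines.** Baseline eGFR is drawn uniformly within the patient's
  category and converted to creatinine by the closed-form CKD-EPI inverse
  at the patient's age and sex, guaranteeing category membership.
* **Injected episodes.** Trajectories rise to a mid-band peak ratio (1.7 /
  2.4 / 3.6 for stages 1–3) on day 2 and decay geometrically to baseline
  (recovery) or to a 1.35 × baseline plateau (non-recovery, which also
  drives the >20% discharge flag). Mid-band peaks keep measurement noise
  from flipping stages across band edges. The ground-truth stage label
  accounts for the 354 µmol/L absolute rule, so a high-baseline patient
  whose stage-2 ratio crosses 354 is labelled (and detected) as stage 3.
* **Measurement noise.** Multiplicative lognormal with sdlog 0.05 in the
  original design sketch; the default here is 0.03. The reason is the
  absolute 48-h criterion: at a baseline of 250–300 µmol/L (eGFR < 30), a
  26 µmol/L day-to-day fluctuation is only ~2 standard deviations at sdlog
  0.05, and daily inpatient sampling would generate spurious stage-1
  episodes in exactly the patients with the worst kidney function. At 0.03
  the spurious-trigger probability is negligible while the noise remains
  visible in the data. The value is configurable.
* **Self-consistent index selection.** A patient without AKI is indexed on
  their *last* study-year admission, which makes a later in-year emergency
  admission impossible for them *by construction* in the real cohort. The
  generator reproduces this by placing non-AKI index admissions in the
  final quarter of the year and scheduling follow-up events beyond the
  year end; AKI patients are indexed on the first AKI admission, so their
  later admissions are unconstrained.
* **Reproducibility.** Every patient draws from counter-based substreams of
  the global seed, so patient i's data are invariant to the cohort size.
  Substream seeds are derived with a 32-bit avalanche hash: feeding
  linearly related seeds to R's Mersenne-Twister seeding produces
  measurably correlated first draws (enough to bias coefficient-recovery
  simulations by several standard errors), which the hash removes.

### What the synthetic tests show — and what they do not

Passing the round-trip test (≥ 99% of patients with injected stage and
prior-episode count recovered) shows the detector implements the stated
criteria exactly, under clean data: guaranteed baselines, mid-band peaks,
small noise. It does not show robustness to the misclassification risks of
real data — sparse testing, missing baselines, assay changes, or genuine
biological ambiguity between AKI and CKD progression. Likewise, coefficient
recovery (each generating log-odds-ratio inside its 95% Wald interval in
~95% of replicates at n = 16453) validates the modelling code under a
correctly specified, independently distributed covariate structure; real
covariates are correlated, which is one reason the synthetic cohort's
apparent C statistic (~0.65–0.67 at the default coefficients) sits below
published values — discrimination depends on the joint covariate
distribution, not only on the coefficients.

## Problem sizes used in tests and the acceptance script

Routine tests run on cohorts of 300–4000 patients; the acceptance script
uses 20 covariate-only replicates at the full n = 16453 for coefficient
recovery, n = 1500 with full laboratory series for the engine round trip,
the published two-by-two counts for the exact odds-ratio checks, an
n = 500 / 50-null-predictor regime with B = 100 for optimism detection, 500
replicates for the Hosmer–Lemeshow type-I error, and an end-to-end
pipeline at n = 4000 with B = 30. These sizes give stable Monte-Carlo
behaviour for each property while keeping a full run in minutes on one
CPU; the full-scale pipeline (n = 16453, B = 500) runs unchanged, only
longer.

## Known limitations

* Urine-output KDIGO criteria, renal-replacement flags as triggers, and
  paediatric eGFR are out of scope (RRT-based stage 3 is supported only via
  the absolute creatinine cut).
* The multinomial sensitivity analysis (readmission and death as separate
  outcomes) is not implemented.
* Deprivation and rurality are consumed as precomputed binary flags;
  deriving them from geography is out of scope.
* The standardised Hosmer–Lemeshow implementation is a documented
  subsample-based stand-in for a cited method whose formula is not restated
  in the source analysis.
* The generator does not model disease progression, correlated
  comorbidities, or informative testing frequency; its role is structural
  fidelity with known truth, not epidemiological realism.
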