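# Shared fixtures, built in code.

# small covariate-only cohort for model tests (fast path, truth columns
# usable directly as predictors)
small_truth_cohort <- function(n = 2500, seed = 101) {
  cfg <- synth_config(n_patients = n, seed = seed)
  g <- generate_covariates(cfg)
  rows <- g$truth
  rows$outcome_90 <- rows$true_outcome
  list(rows = rows, config = cfg, intercept = g$intercept)
}

# a hand-built creatinine series: stable baseline then a configurable rise
series_with_rise <- function(baseline = 80, peak, peak_day = 100,
                             baseline_days = c(10, 40, 70)) {
  times <- c(baseline_days, peak_day)
  values <- c(rep(baseline, length(baseline_days)), peak)
  list(times = times, values = values)
}

# synthetic config for end-to-end pipeline tests at small n: rare flags are
# made common enough that no candidate predictor has an empty outcome cell
# (which would be a legitimate separation error at paper scale but is just
# a small-sample artifact here)
robust_synth_config <- function(n, seed) {
  synth_config(
    n_patients = n, seed = seed,
    stage_mix = c(1, 1, 1) / 3,
    comorbidity_prevalences = c(
      cancer = 0.15, cardiac_failure = 0.15, cerebrovascular = 0.15,
      dementia = 0.15, diabetes = 0.15, hemiplegia = 0.15, liver = 0.15,
      mi = 0.15, peptic_ulcer = 0.15, pvd = 0.15, pulmonary = 0.15,
      rheumatic = 0.15),
    prevalences = c(male = 0.45, residential_care = 0.15, deprived = 0.15,
                    rural = 0.30, emergency = 0.60, medical_ward = 0.50,
                    icu = 0.10, chronic_rrt = 0.005))
}

# null-predictor design for overfitting / elimination tests
null_design <- function(n, p, event_rate = 0.3, seed = 1) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  x <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("x", seq_len(p))))
  rows <- data.frame(x, outcome_90 = rbinom(n, 1, event_rate))
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  list(rows = rows,
       terms = data.frame(group = colnames(x), term = colnames(x)))
}
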