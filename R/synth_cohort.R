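# Synthetic linked-cohort generator.
#
# Emulates the data structure the analysis assumes: serial creatinine from a
# single laboratory (sparse outpatient testing plus daily inpatient
# sampling), hospital admission records with ICD-10 codes, death dates,
# demographic/social flags, and a binary 90-day readmission-or-death outcome
# drawn from a logistic model with configurable coefficients.  Every patient
# carries ground-truth labels (injected AKI stage, prior episode count, true
# linear predictor) so each downstream stage can be tested against truth.

EPOCH_DATE <- as.Date("2003-01-01")

# mid-band peak/baseline ratios used when injecting an episode of each stage
STAGE_PEAK_RATIO <- c(1.7, 2.4, 3.6)
NONRECOVERY_RATIO <- 1.35   # plateau after a non-recovering episode
MILD_WORSENING_RATIO <- 1.28  # in-admission creatinine drift without AKI

#' Configuration for the synthetic cohort generator
#'
#' Defaults reproduce the composition of the source cohort: 16453 patients,
#' 15.9% with an index AKI episode staged 65.5/21.9/12.6% across stages
#' 1-3, baseline eGFR categories at 59.8/24.4/11.5/4.3%
#' (>=60/45-59/30-44/<30), published comorbidity prevalences, an 18.6%
#' 90-day event rate, and 11.8% of events occurring as death without
#' readmission.  Outcome coefficients default to the best-stepwise-model
#' odds ratios (log scale) on the encoded terms of [candidate_terms()].
#'
#' @param n_patients Number of patients (>= 1).
#' @param aki_prevalence Fraction with an index AKI episode.
#' @param stage_mix Fractions over injected stages 1-3 (sums to 1).
#' @param egfr_category_mix Fractions over baseline eGFR categories
#'   `>=60, 45-59, 30-44, <30` (sums to 1).
#' @param comorbidity_prevalences Named fractions for the 12 comorbidities.
#' @param outcome_coefficients Named log-odds-ratios on encoded term names.
#' @param target_event_rate Marginal outcome probability the intercept is
#'   calibrated to by root-finding.
#' @param horizon_days Outcome horizon (default 90).
#' @param seed Integer seed; patient `i` gets a counter-based substream so
#'   its data do not depend on `n_patients`.
#' @param death_without_readmission Fraction of events that are deaths with
#'   no preceding readmission.
#' @param noise_sd Multiplicative lognormal measurement noise (sdlog).
#'   Small enough that neither the 1.5x ratio rules nor the 26 umol/L
#'   48-hour rise fire spuriously at high baseline creatinine.
#' @param outpatient_gap_mean Mean exponential gap between community
#'   creatinine tests, days.
#' @param nonrecovery_aki,nonrecovery_noaki Probability of a >20% discharge
#'   creatinine worsening for patients with / without an index episode.
#' @param prior_aki_dist Probabilities of 0, 1, 2 prior AKI episodes.
#' @param adm_past_year_dist Probabilities of 0, 1, 2, 3+ admissions in the
#'   prior year (3+ adds a Poisson(0.7) excess, capped at 8).
#' @param prevalences Named fractions for binary demographic/admission
#'   flags (`male`, `residential_care`, `deprived`, `rural`, `emergency`,
#'   `medical_ward`, `icu`, `chronic_rrt`).
#' @param age_mean,age_sd Normal age distribution, truncated to 18-100.
#' @param los_meanlog,los_sdlog Lognormal index length of stay, days.
#' @return A validated `synth_config` list.
#' @export
synth_config <- function(n_patients = 16453,
                         aki_prevalence = 0.159,
                         stage_mix = c(0.655, 0.219, 0.126),
                         egfr_category_mix = c(0.598, 0.244, 0.115, 0.043),
                         comorbidity_prevalences = c(
                           cancer = 0.084, cardiac_failure = 0.055,
                           cerebrovascular = 0.049, dementia = 0.016,
                           diabetes = 0.068, hemiplegia = 0.006,
                           liver = 0.013, mi = 0.054, peptic_ulcer = 0.022,
                           pvd = 0.037, pulmonary = 0.064, rheumatic = 0.023),
                         outcome_coefficients = c(
                           age10c = log(1.17), residential_care = log(1.37),
                           rural = log(0.86), adm_past_year = log(1.23),
                           emergency = log(1.89), aki1 = log(1.50),
                           aki2 = log(2.23), aki3 = log(2.80),
                           egfr10c = log(0.87), egfr10c_sq = log(1.01),
                           cancer = log(1.59), cardiac_failure = log(1.42),
                           diabetes = log(1.38), pulmonary = log(1.47)),
                         target_event_rate = 0.186,
                         horizon_days = 90,
                         seed = 1L,
                         death_without_readmission = 0.118,
                         noise_sd = 0.03,
                         outpatient_gap_mean = 60,
                         nonrecovery_aki = 0.30,
                         nonrecovery_noaki = 0.066,
                         prior_aki_dist = c(0.894, 0.086, 0.020),
                         adm_past_year_dist = c(0.751, 0.150, 0.053, 0.046),
                         prevalences = c(male = 0.434, residential_care = 0.045,
                                         deprived = 0.084, rural = 0.271,
                                         emergency = 0.613, medical_ward = 0.514,
                                         icu = 0.028, chronic_rrt = 0.005),
                         age_mean = 68, age_sd = 16,
                         los_meanlog = log(4), los_sdlog = 0.9) {
  cfg <- as.list(environment())
  fracs <- c(aki_prevalence, stage_mix, egfr_category_mix,
             comorbidity_prevalences, target_event_rate,
             death_without_readmission, nonrecovery_aki, nonrecovery_noaki,
             prior_aki_dist, adm_past_year_dist, prevalences)
  if (any(fracs < 0 | fracs > 1)) stop("all fractions must lie in [0, 1]")
  if (abs(sum(stage_mix) - 1) > 1e-9) stop("stage_mix must sum to 1")
  if (abs(sum(egfr_category_mix) - 1) > 1e-9)
    stop("egfr_category_mix must sum to 1")
  if (abs(sum(prior_aki_dist) - 1) > 1e-9) stop("prior_aki_dist must sum to 1")
  if (abs(sum(adm_past_year_dist) - 1) > 1e-9)
    stop("adm_past_year_dist must sum to 1")
  if (n_patients < 1) stop("n_patients must be >= 1")
  class(cfg) <- "synth_config"
  cfg
}

# Draw one patient's covariates and admission frame (phase-1 substream).
# The same draws occur in covariate-only and full generation, so truth
# tables agree between the two paths.
draw_patient_covariates <- function(cfg, i) {
  rng <- local_rng(substream_seed(cfg$seed, i, phase = 1L))
  on.exit(restore_rng(rng))
  pv <- cfg$prevalences
  age <- min(max(stats::rnorm(1, cfg$age_mean, cfg$age_sd), 18), 100)
  male <- stats::rbinom(1, 1, pv[["male"]])
  egfr_cat <- sample.int(4, 1, prob = cfg$egfr_category_mix)
  egfr <- switch(egfr_cat,
                 stats::runif(1, 60, 105),
                 stats::runif(1, 45, 59.9),
                 stats::runif(1, 30, 44.9),
                 stats::runif(1, 18, 29.9))
  baseline_creat <- creatinine_for_egfr(egfr, age, female = male == 0)
  aki <- stats::rbinom(1, 1, cfg$aki_prevalence)
  stage_req <- if (aki == 1) sample.int(3, 1, prob = cfg$stage_mix) else 0L
  # effective truth stage accounts for the absolute 354 umol/L stage-3 cut
  aki_stage <- if (aki == 1)
    kdigo_stage(baseline_creat * STAGE_PEAK_RATIO[stage_req], baseline_creat)
  else 0L
  prior_aki <- sample.int(3, 1, prob = cfg$prior_aki_dist) - 1L
  nonrec_p <- if (aki == 1) cfg$nonrecovery_aki else cfg$nonrecovery_noaki
  nonrecovery <- stats::rbinom(1, 1, nonrec_p)
  adm_py <- sample.int(4, 1, prob = cfg$adm_past_year_dist) - 1L
  if (adm_py == 3L) adm_py <- min(3L + stats::rpois(1, 0.7), 8L)
  los <- max(1, round(stats::rlnorm(1, cfg$los_meanlog, cfg$los_sdlog)))
  los <- min(los, 60)
  if (aki == 1 || nonrecovery == 1) los <- max(los, 6)
  comorb <- stats::rbinom(length(cfg$comorbidity_prevalences), 1,
                          cfg$comorbidity_prevalences)
  names(comorb) <- names(cfg$comorbidity_prevalences)
  c(list(patient_id = i, age = age, male = male,
         residential_care = stats::rbinom(1, 1, pv[["residential_care"]]),
         deprived = stats::rbinom(1, 1, pv[["deprived"]]),
         rural = stats::rbinom(1, 1, pv[["rural"]]),
         chronic_rrt = stats::rbinom(1, 1, pv[["chronic_rrt"]]),
         baseline_egfr = egfr, baseline_creatinine = baseline_creat,
         aki_stage = as.integer(aki_stage), stage_req = as.integer(stage_req),
         prior_aki_count = prior_aki, nonrecovery = nonrecovery,
         adm_past_year = adm_py, length_of_stay = los,
         emergency = stats::rbinom(1, 1, pv[["emergency"]]),
         medical_ward = stats::rbinom(1, 1, pv[["medical_ward"]]),
         icu = stats::rbinom(1, 1, pv[["icu"]]),
         # a patient without AKI is indexed on their *last* study-year
         # admission, so no later in-year admission can exist for them;
         # placing these indexes in the final quarter lets follow-up events
         # fall beyond the study year and keeps the rule self-consistent
         admit_time = if (aki == 1) sample(10:355, 1) else sample(280:355, 1)),
    as.list(comorb))
}

#' Generate the truth/covariate table only
#'
#' Fast path for simulation studies that need the predictor table and the
#' Bernoulli outcomes but not the laboratory series: identical covariate and
#' outcome draws to [generate_cohort()] under the same config.
#'
#' @param config A [synth_config()].
#' @return List with `truth` (data.frame; one row per patient, including
#'   `true_linear_predictor`, `true_outcome`, `event_day`,
#'   `death_without_readmission`) and `intercept` (the calibrated value).
#' @export
generate_covariates <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  rows <- lapply(seq_len(config$n_patients),
                 function(i) draw_patient_covariates(config, i))
  truth <- data.table::rbindlist(rows)
  truth <- as.data.frame(truth)
  x <- term_matrix(truth, names(config$outcome_coefficients))
  lp <- drop(x %*% config$outcome_coefficients)
  f <- function(b) mean(stats::plogis(lp + b)) - config$target_event_rate
  if (f(-30) > 0 || f(30) < 0)
    stop("infeasible calibration: target event rate ", config$target_event_rate,
         " unreachable given the outcome coefficients")
  intercept <- stats::uniroot(f, c(-30, 30), tol = 1e-10)$root
  truth$true_linear_predictor <- lp + intercept
  p <- stats::plogis(truth$true_linear_predictor)
  out <- matrix(NA_real_, nrow = config$n_patients, ncol = 3)
  for (i in seq_len(config$n_patients)) {
    rng <- local_rng(substream_seed(config$seed, i, phase = 2L))
    yi <- stats::rbinom(1, 1, p[i])
    death <- if (yi == 1) stats::rbinom(1, 1, config$death_without_readmission) else 0L
    # readmissions for non-AKI patients must land beyond the study year
    # (otherwise they would themselves become the index admission)
    lb <- if (truth$aki_stage[i] > 0 || yi == 0) 1L else
      max(1L, 366L - (truth$admit_time[i] + truth$length_of_stay[i]))
    eday <- if (yi == 1) {
      if (death == 1L) sample.int(config$horizon_days, 1)
      else lb + sample.int(config$horizon_days - lb + 1L, 1) - 1L
    } else NA_integer_
    restore_rng(rng)
    out[i, ] <- c(yi, death, eday)
  }
  truth$true_outcome <- as.integer(out[, 1])
  truth$death_without_readmission <- as.integer(out[, 2])
  truth$event_day <- as.integer(out[, 3])
  names(truth)[names(truth) == "aki_stage"] <- "true_aki_stage"
  names(truth)[names(truth) == "prior_aki_count"] <- "true_prior_episode_count"
  names(truth)[names(truth) == "baseline_creatinine"] <- "true_baseline_creatinine"
  # duplicate plain predictor columns so the truth table can be fed straight
  # into term_matrix()/fit_logistic() for oracle fits
  truth$aki_stage <- truth$true_aki_stage
  truth$prior_aki_count <- truth$true_prior_episode_count
  list(truth = truth, intercept = intercept)
}

#' Injected creatinine trajectory for one AKI episode
#'
#' Daily creatinine values (ratio-space shape times baseline): a qualifying
#' first value at 1.55 times baseline (or the peak ratio if smaller), a
#' geometric rise to the stage's mid-band peak ratio (1.7 / 2.4 / 3.6 for
#' stages 1-3) on day 2, then geometric decay to baseline (recovery) or to
#' a 1.35 x baseline plateau (non-recovery, i.e. a final value above the
#' 1.2 x baseline non-recovery threshold).
#'
#' @param baseline Baseline creatinine, umol/L (> 0).
#' @param stage Intended KDIGO stage 1-3.
#' @param start_day First day of the episode.
#' @param duration_days Episode length in days (4-90).
#' @param recovery Logical; FALSE leaves creatinine > 1.2 x baseline.
#' @return data.frame with `day`, `value` and `is_peak` (the peak test is
#'   marked so callers can exempt it from measurement noise).
#' @export
inject_aki_trajectory <- function(baseline, stage, start_day, duration_days,
                                  recovery = TRUE) {
  if (!stage %in% 1:3) stop("stage must be 1, 2 or 3")
  stopifnot(baseline > 0, duration_days <= 90, duration_days >= 4)
  peak_ratio <- STAGE_PEAK_RATIO[stage]
  end_ratio <- if (recovery) 1.0 else NONRECOVERY_RATIO
  days <- 0:duration_days
  peak_day <- 2
  ratio <- numeric(length(days))
  ratio[1] <- min(1.55, peak_ratio)
  ratio[days > 0 & days <= peak_day] <-
    exp(log(ratio[1]) + (log(peak_ratio) - log(ratio[1])) *
          days[days > 0 & days <= peak_day] / peak_day)
  dd <- days[days > peak_day]
  ratio[days > peak_day] <-
    exp(log(peak_ratio) + (log(end_ratio) - log(peak_ratio)) *
          (dd - peak_day) / (duration_days - peak_day))
  data.frame(day = start_day + days, value = baseline * ratio,
             is_peak = days == peak_day)
}

# Build one patient's laboratory series, admissions, and death record
# (phase-3 substream).  `cov` is the phase-1 covariate list plus outcome
# fields from generate_covariates().
build_patient_records <- function(cfg, cov) {
  i <- cov$patient_id
  rng <- local_rng(substream_seed(cfg$seed, i, phase = 3L))
  on.exit(restore_rng(rng))
  a0 <- cov$admit_time
  los <- cov$length_of_stay
  discharge <- a0 + los
  base <- cov$true_baseline_creatinine
  aki <- cov$true_aki_stage > 0

  # ---- injected episodes ----------------------------------------------
  episodes <- list()
  if (aki) {
    dur <- max(4, min(los - 1, 10))
    episodes[[1]] <- list(start = a0 + 1, duration = dur,
                          stage = cov$stage_req,
                          recovery = cov$nonrecovery == 0)
  }
  if (cov$true_prior_episode_count > 0) {
    grid <- seq(a0 - 1000, a0 - 150, by = 160)
    starts <- sort(sample(grid, cov$true_prior_episode_count))
    for (s in starts)
      episodes[[length(episodes) + 1]] <- list(
        start = s, duration = 10,
        stage = sample.int(3, 1, prob = cfg$stage_mix), recovery = TRUE)
  }
  prior_ep_starts <- vapply(episodes, `[[`, numeric(1), "start")
  prior_ep_starts <- prior_ep_starts[prior_ep_starts < a0]

  # ---- admissions ------------------------------------------------------
  adm <- list(data.frame(patient_id = i, admit_time = a0,
                         discharge_time = discharge,
                         emergency = cov$emergency,
                         medical_ward = cov$medical_ward, icu = cov$icu,
                         icd10 = ""))
  if (cov$adm_past_year > 0) {
    slots <- seq(a0 - 364, a0 - 12, by = 18)
    # keep admissions clear of injected episode windows so no prior-year
    # admission can overlap an AKI episode and usurp the index selection
    for (s in prior_ep_starts) slots <- slots[abs(slots - s) > 16]
    starts <- sort(sample(slots, min(cov$adm_past_year, length(slots))))
    adm[[length(adm) + 1]] <- data.frame(
      patient_id = i, admit_time = starts,
      discharge_time = starts + 1 + stats::rpois(length(starts), 2),
      emergency = stats::rbinom(length(starts), 1, 0.6),
      medical_ward = stats::rbinom(length(starts), 1, 0.5),
      icu = 0L, icd10 = "")
  }
  comorb_names <- names(cfg$comorbidity_prevalences)
  present <- comorb_names[vapply(comorb_names, function(nm) cov[[nm]] == 1, logical(1))]
  if (length(present) > 0) {
    codes <- paste(vapply(present, comorbidity_example_code, character(1)),
                   collapse = ";")
    start <- a0 - sample(1100:1780, 1)
    adm[[length(adm) + 1]] <- data.frame(
      patient_id = i, admit_time = start, discharge_time = start + 2,
      emergency = 1L, medical_ward = 1L, icu = 0L, icd10 = codes)
  }
  ep_windows <- if (length(episodes)) data.frame(
    patient_id = i,
    start_day = vapply(episodes, `[[`, numeric(1), "start"),
    end_day = vapply(episodes, function(e) e$start + e$duration, numeric(1)),
    stage = vapply(episodes, `[[`, integer(1), "stage")) else NULL

  # ---- laboratory series ----------------------------------------------
  horizon_end <- a0 + 365
  gaps <- stats::rexp(ceiling((horizon_end + 1460) / cfg$outpatient_gap_mean * 2) + 4,
                      rate = 1 / cfg$outpatient_gap_mean)
  out_days <- round(a0 - 1460 + cumsum(gaps))
  out_days <- out_days[out_days < horizon_end]
  out_days <- c(out_days, a0 - sample(30:60, 1))   # guaranteed baseline test
  for (e in episodes) if (e$start < a0 - 90)
    out_days <- c(out_days, e$start - 30)          # baseline support for priors
  inpat_days <- unlist(lapply(adm, function(d)
    unlist(Map(seq, d$admit_time, d$discharge_time))))
  # drop community draws inside or flanking episode windows and just before
  # an admission with a creatinine step, to keep short-window rules clean
  for (e in episodes)
    out_days <- out_days[out_days < e$start - 3 | out_days > e$start + e$duration + 3]
  if (!aki && cov$nonrecovery == 1)
    out_days <- out_days[out_days < a0 - 3 | out_days >= a0]
  days <- sort(unique(c(out_days, inpat_days)))
  days <- days[days >= a0 - 1460 & days < horizon_end]
  value <- rep(base, length(days))
  is_peak <- rep(FALSE, length(days))

  if (!aki && cov$nonrecovery == 1)        # persistent non-AKI worsening
    value[days >= a0] <- base * MILD_WORSENING_RATIO
  for (e in episodes) {
    traj <- inject_aki_trajectory(base, e$stage, e$start, e$duration, e$recovery)
    if (!e$recovery)                       # plateau continues after episode
      value[days > e$start + e$duration] <- base * NONRECOVERY_RATIO
    m <- match(days, traj$day)
    hit <- !is.na(m)
    value[hit] <- traj$value[m[hit]]
    is_peak[hit] <- traj$is_peak[m[hit]]
    need <- setdiff(traj$day, days)        # trajectory days not yet sampled
    if (length(need)) {
      days <- c(days, need)
      value <- c(value, traj$value[match(need, traj$day)])
      is_peak <- c(is_peak, traj$is_peak[match(need, traj$day)])
      o <- order(days)
      days <- days[o]; value <- value[o]; is_peak <- is_peak[o]
    }
  }
  noise <- exp(stats::rnorm(length(value), 0, cfg$noise_sd))
  value <- ifelse(is_peak, value, value * noise)

  # ---- outcome events --------------------------------------------------
  death_time <- NA_real_
  if (cov$true_outcome == 1) {
    etime <- discharge + cov$event_day
    if (cov$death_without_readmission == 1) {
      death_time <- etime
    } else {
      code <- readmission_cause_code(aki, cov$baseline_egfr)
      adm[[length(adm) + 1]] <- data.frame(
        patient_id = i, admit_time = etime,
        discharge_time = etime + 1 + stats::rpois(1, 3),
        emergency = 1L, medical_ward = 1L, icu = 0L, icd10 = code)
    }
  } else {
    u <- stats::runif(1)
    if (u < 0.08) {                        # planned admission inside horizon
      lb <- if (aki) 1L else max(1L, 366L - discharge)
      etime <- discharge + lb + sample.int(cfg$horizon_days - lb + 1L, 1) - 1L
      adm[[length(adm) + 1]] <- data.frame(
        patient_id = i, admit_time = etime, discharge_time = etime + 1,
        emergency = 0L, medical_ward = 0L, icu = 0L, icd10 = "Z50.9")
    } else if (u < 0.18) {                 # emergency admission after horizon
      etime <- discharge + cfg$horizon_days + sample.int(90, 1) + 4
      adm[[length(adm) + 1]] <- data.frame(
        patient_id = i, admit_time = etime,
        discharge_time = etime + 1 + stats::rpois(1, 3),
        emergency = 1L, medical_ward = 1L, icu = 0L, icd10 = "J18.9")
    } else if (u < 0.20) {                 # late death
      death_time <- discharge + cfg$horizon_days + sample.int(200, 1) + 9
    }
  }
  if (!is.na(death_time)) {
    keep <- days <= death_time
    days <- days[keep]; value <- value[keep]
  }
  list(labs = data.frame(patient_id = i, time = days,
                         creatinine = round(pmax(value, 5), 1)),
       admissions = data.table::rbindlist(adm),
       death = if (!is.na(death_time))
         data.frame(patient_id = i, death_time = death_time) else NULL,
       episode_windows = ep_windows)
}

# representative ICD-10 code for each generated comorbidity
comorbidity_example_code <- function(name) {
  switch(name,
         cancer = "C34.9", cardiac_failure = "I50.0",
         cerebrovascular = "I63.9", dementia = "F03",
         diabetes = "E11.9", hemiplegia = "G81.9", liver = "K74.6",
         mi = "I21.9", peptic_ulcer = "K27.9", pvd = "I73.9",
         pulmonary = "J44.9", rheumatic = "M05.9",
         stop("unknown comorbidity: ", name))
}

# readmission diagnosis: acute pulmonary oedema (I50) at the observed rates
# by AKI / baseline-eGFR group, otherwise a spread of common causes
readmission_cause_code <- function(aki, egfr) {
  p_oedema <- if (aki && egfr < 60) 0.266 else if (!aki && egfr < 60) 0.131
              else if (aki) 0.070 else 0.040
  if (stats::runif(1) < p_oedema) return("I50.1;N17.9")
  sample(c("J18.9", "J22", "I21.0", "I20.0", "I63.9", "G45.9",
           "K52.9", "N39.0", "R07.4", "L03.1"), 1,
         prob = c(0.18, 0.07, 0.10, 0.05, 0.06, 0.04, 0.15, 0.15, 0.12, 0.08))
}

#' Generate a complete synthetic cohort
#'
#' Draws patient covariates, calibrates the outcome-model intercept to the
#' target event rate by root-finding, draws outcomes, and materialises
#' laboratory series (community testing at exponential gaps plus daily
#' inpatient sampling, lognormal measurement noise), admission records with
#' ICD-10 comorbidity and readmission-cause codes, and death dates.  All
#' randomness derives from per-patient substreams of `config$seed`, so
#' patient `i` is reproducible and independent of `n_patients`.
#'
#' @param config A [synth_config()].
#' @return List of class `synth_cohort` with `labs`, `admissions`, `deaths`,
#'   `demographics`, `truth`, `episode_windows` (injected truth windows),
#'   `intercept` and `config`.
#' @export
generate_cohort <- function(config) {
  gc0 <- generate_covariates(config)
  truth <- gc0$truth
  recs <- lapply(seq_len(config$n_patients), function(i) {
    cov <- as.list(truth[i, ])
    names(cov)[names(cov) == "true_aki_stage"] <- "true_aki_stage"
    build_patient_records(config, cov)
  })
  labs <- as.data.frame(data.table::rbindlist(lapply(recs, `[[`, "labs")))
  admissions <- as.data.frame(data.table::rbindlist(lapply(recs, `[[`, "admissions")))
  deaths <- as.data.frame(data.table::rbindlist(
    Filter(Negate(is.null), lapply(recs, `[[`, "death"))))
  if (nrow(deaths) == 0)
    deaths <- data.frame(patient_id = integer(0), death_time = numeric(0))
  ep <- as.data.frame(data.table::rbindlist(
    Filter(Negate(is.null), lapply(recs, `[[`, "episode_windows"))))
  demographics <- truth[, c("patient_id", "age", "male", "residential_care",
                            "deprived", "rural", "chronic_rrt")]
  structure(list(labs = labs, admissions = admissions, deaths = deaths,
                 demographics = demographics, truth = truth,
                 episode_windows = ep, intercept = gc0$intercept,
                 config = config), class = "synth_cohort")
}

#' @export
print.synth_cohort <- function(x, ...) {
  cat(sprintf("Synthetic cohort: %d patients, %d creatinine results, %d admissions\n",
              nrow(x$truth), nrow(x$labs), nrow(x$admissions)))
  cat(sprintf("  injected AKI: %d patients; realised event rate %.3f (target %.3f)\n",
              sum(x$truth$true_aki_stage > 0), mean(x$truth$true_outcome),
              x$config$target_event_rate))
  invisible(x)
}

#' Write a synthetic cohort to CSV files
#'
#' Emits `labs.csv` (ISO-8601 dates, creatinine in umol/L),
#' `admissions.csv` (semicolon-delimited ICD-10 codes), `deaths.csv`,
#' `demographics.csv` and `truth.csv` under `dir`.  Day 0 corresponds to
#' 2003-01-01.
#'
#' @param cohort A `synth_cohort`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort_csvs <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  labs <- data.frame(patient_id = cohort$labs$patient_id,
                     date = format(EPOCH_DATE + cohort$labs$time),
                     creatinine_umol_l = cohort$labs$creatinine)
  utils::write.csv(labs, file.path(dir, "labs.csv"), row.names = FALSE)
  adm <- cohort$admissions
  adm_out <- data.frame(patient_id = adm$patient_id,
                        admit_date = format(EPOCH_DATE + adm$admit_time),
                        discharge_date = format(EPOCH_DATE + adm$discharge_time),
                        emergency = adm$emergency, medical_ward = adm$medical_ward,
                        icu = adm$icu, icd10 = adm$icd10)
  utils::write.csv(adm_out, file.path(dir, "admissions.csv"), row.names = FALSE)
  deaths <- data.frame(patient_id = cohort$deaths$patient_id,
                       death_date = format(EPOCH_DATE + cohort$deaths$death_time))
  utils::write.csv(deaths, file.path(dir, "deaths.csv"), row.names = FALSE)
  utils::write.csv(cohort$demographics, file.path(dir, "demographics.csv"),
                   row.names = FALSE)
  utils::write.csv(cohort$truth, file.path(dir, "truth.csv"), row.names = FALSE)
  invisible(dir)
}

#' Read cohort CSV files written by [write_cohort_csvs()]
#'
#' @param dir Directory holding the CSV files.
#' @return List with `labs`, `admissions`, `deaths`, `demographics` in the
#'   internal day-number representation (day 0 = 2003-01-01).
#' @export
read_cohort_csvs <- function(dir) {
  labs_raw <- utils::read.csv(file.path(dir, "labs.csv"))
  labs <- data.frame(patient_id = labs_raw$patient_id,
                     time = as.numeric(as.Date(labs_raw$date) - EPOCH_DATE),
                     creatinine = labs_raw$creatinine_umol_l)
  adm_raw <- utils::read.csv(file.path(dir, "admissions.csv"),
                             colClasses = c(icd10 = "character"))
  admissions <- data.frame(patient_id = adm_raw$patient_id,
                           admit_time = as.numeric(as.Date(adm_raw$admit_date) - EPOCH_DATE),
                           discharge_time = as.numeric(as.Date(adm_raw$discharge_date) - EPOCH_DATE),
                           emergency = adm_raw$emergency,
                           medical_ward = adm_raw$medical_ward,
                           icu = adm_raw$icu, icd10 = adm_raw$icd10)
  deaths_raw <- utils::read.csv(file.path(dir, "deaths.csv"))
  deaths <- data.frame(patient_id = deaths_raw$patient_id,
                       death_time = if (nrow(deaths_raw))
                         as.numeric(as.Date(deaths_raw$death_date) - EPOCH_DATE)
                       else numeric(0))
  demographics <- utils::read.csv(file.path(dir, "demographics.csv"))
  list(labs = labs, admissions = admissions, deaths = deaths,
       demographics = demographics)
}
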