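# Cohort assembly: index admission selection, candidate predictors, and
# outcome definitions.

# Quan ICD-10 prefix mapping for the 12 Charlson comorbidity groups used as
# binary candidate predictors.  Codes are matched on normalised (dot-free,
# upper-case) prefixes.
quan_charlson_map <- function() {
  list(
    mi = c("I21", "I22", "I252"),
    cardiac_failure = c("I099", "I110", "I130", "I132", "I255", "I420",
                        "I425", "I426", "I427", "I428", "I429", "I43",
                        "I50", "P290"),
    pvd = c("I70", "I71", "I731", "I738", "I739", "I771", "I790", "I792",
            "K551", "K558", "K559", "Z958", "Z959"),
    cerebrovascular = c("G45", "G46", "H340", paste0("I6", 0:9)),
    dementia = c("F00", "F01", "F02", "F03", "F051", "G30", "G311"),
    pulmonary = c("I278", "I279", paste0("J4", 0:7), paste0("J6", 0:7),
                  "J684", "J701", "J703"),
    rheumatic = c("M05", "M06", "M315", "M32", "M33", "M34", "M351", "M353",
                  "M360"),
    peptic_ulcer = c("K25", "K26", "K27", "K28"),
    liver = c("B18", "K700", "K701", "K702", "K703", "K709", "K713",
              "K714", "K715", "K717", "K73", "K74", "K760", "K762",
              "K763", "K764", "K768", "K769", "Z944"),
    diabetes = c("E10", "E11", "E12", "E13", "E14"),
    hemiplegia = c("G041", "G114", "G801", "G802", "G81", "G82", "G830",
                   "G831", "G832", "G833", "G834", "G839"),
    cancer = c(sprintf("C%02d", c(0:26, 30:34, 37:41, 43, 45:58, 60:76,
                                  81:85, 88, 90:97))))
}

normalise_icd10 <- function(codes) toupper(gsub("[. ]", "", codes))

check_icd10 <- function(codes) {
  bad <- codes[!grepl("^[A-Z][0-9]{2}[0-9A-Z]*$", normalise_icd10(codes))]
  if (length(bad))
    stop("malformed ICD-10 code(s): ", paste(unique(bad), collapse = ", "))
  invisible(codes)
}

matches_prefix <- function(codes, prefixes) {
  norm <- normalise_icd10(codes)
  any(vapply(norm, function(cd) any(startsWith(cd, prefixes)), logical(1)))
}

split_codes <- function(icd10_field) {
  codes <- unlist(strsplit(icd10_field, ";", fixed = TRUE))
  codes <- trimws(codes)
  codes[nzchar(codes)]
}

#' Classify a readmission by its ICD-10 diagnosis codes
#'
#' Matches the code list against the four cause groups: acute coronary
#' syndrome (I20-I22), cerebrovascular disease (G45, I60-I67), lower
#' respiratory tract infection (J10-J18, J20-J22), and acute pulmonary
#' oedema in the context of heart failure (I50).  A readmission may match
#' several groups.
#'
#' @param icd10_codes Character vector of ICD-10 codes (possibly empty);
#'   the first code is taken as the main diagnosis.
#' @return List with `categories` (character vector, possibly empty),
#'   `pulmonary_oedema_any` and `pulmonary_oedema_main` (logical).
#' @export
classify_readmission_cause <- function(icd10_codes) {
  icd10_codes <- icd10_codes[nzchar(icd10_codes)]
  if (length(icd10_codes) == 0)
    return(list(categories = character(0), pulmonary_oedema_any = FALSE,
                pulmonary_oedema_main = FALSE))
  check_icd10(icd10_codes)
  norm <- normalise_icd10(icd10_codes)
  groups <- list(
    acute_coronary_syndrome = c("I20", "I21", "I22"),
    cerebrovascular = c("G45", paste0("I6", 0:7)),
    lower_respiratory_infection = c(paste0("J1", 0:8), paste0("J2", 0:2)),
    pulmonary_oedema = "I50")
  cats <- names(groups)[vapply(groups, function(p) matches_prefix(norm, p),
                               logical(1))]
  list(categories = cats,
       pulmonary_oedema_any = "pulmonary_oedema" %in% cats,
       pulmonary_oedema_main = startsWith(norm[1], "I50"))
}

# merge same-day transfers: an admission starting on the day a previous one
# ended is a continuation of the same hospital stay
merge_transfers <- function(adm) {
  if (nrow(adm) < 2) return(adm)
  adm <- adm[order(adm$admit_time), , drop = FALSE]
  out <- adm[1, , drop = FALSE]
  for (k in 2:nrow(adm)) {
    last <- nrow(out)
    if (adm$admit_time[k] <= out$discharge_time[last]) {
      out$discharge_time[last] <- max(out$discharge_time[last],
                                      adm$discharge_time[k])
      out$emergency[last] <- max(out$emergency[last], adm$emergency[k])
      out$medical_ward[last] <- max(out$medical_ward[last], adm$medical_ward[k])
      out$icu[last] <- max(out$icu[last], adm$icu[k])
      joined <- paste(c(out$icd10[last], adm$icd10[k]), collapse = ";")
      out$icd10[last] <- gsub("^;|;$", "", joined)
    } else {
      out <- rbind(out, adm[k, , drop = FALSE])
    }
  }
  out
}

#' Select the index admission for one patient
#'
#' The index admission is the first study-year admission overlapping an AKI
#' episode, or, if no study-year admission has AKI, the last study-year
#' admission.
#'
#' @param admissions Data.frame of one patient's admissions (`admit_time`,
#'   `discharge_time`, ...).
#' @param episodes Data.frame of the patient's detected AKI episodes
#'   (`start_time`, `end_time`).
#' @param study_window Numeric `c(start, end)` in days; admissions with
#'   `admit_time` in `[start, end)` are candidates.
#' @return The selected admission row, or `NULL` when the patient has no
#'   study-year admission.
#' @export
select_index_admission <- function(admissions, episodes,
                                   study_window = c(0, 365)) {
  cand <- admissions[admissions$admit_time >= study_window[1] &
                       admissions$admit_time < study_window[2], , drop = FALSE]
  if (nrow(cand) == 0) return(NULL)
  cand <- cand[order(cand$admit_time), , drop = FALSE]
  if (nrow(episodes) > 0) {
    overlaps <- vapply(seq_len(nrow(cand)), function(k)
      any(episodes$start_time <= cand$discharge_time[k] &
            episodes$end_time >= cand$admit_time[k]), logical(1))
    if (any(overlaps)) return(cand[which(overlaps)[1], , drop = FALSE])
  }
  cand[nrow(cand), , drop = FALSE]
}

#' Define composite outcomes after the index discharge
#'
#' The composite outcome at horizon `h` is an emergency (non-elective)
#' readmission or death with event time in `(discharge, discharge + h]`
#' (inclusive at the horizon day).  The pulmonary-oedema outcome requires
#' an emergency readmission within 90 days carrying an I50 code.
#'
#' @param index_discharge Discharge time of the index admission, days.
#' @param later_admissions Data.frame of the patient's other admissions
#'   (`admit_time`, `emergency`, `icd10`).
#' @param death_time Death time in days, or `NA`.
#' @param horizons Numeric vector of horizons (default `c(30, 60, 90)`).
#' @return List with one `outcome_<h>` flag per horizon,
#'   `outcome_pulm_oedema_90`, `readmission_cause` (comma-joined categories
#'   of the first qualifying readmission, or `""`), and
#'   `first_readmission_time`.
#' @export
define_outcomes <- function(index_discharge, later_admissions, death_time,
                            horizons = c(30, 60, 90)) {
  stopifnot(all(horizons > 0))
  adm <- later_admissions
  if (nrow(adm) > 0 && any(adm$admit_time < index_discharge))
    stop("readmission before index discharge: data error")
  readm <- adm[adm$emergency == 1, , drop = FALSE]
  readm <- readm[order(readm$admit_time), , drop = FALSE]
  first_t <- if (nrow(readm)) readm$admit_time[1] else NA_real_
  out <- list()
  for (h in horizons) {
    hit_readm <- !is.na(first_t) && first_t > index_discharge &&
      first_t <= index_discharge + h
    hit_death <- !is.na(death_time) && death_time > index_discharge &&
      death_time <= index_discharge + h
    out[[paste0("outcome_", h)]] <- as.integer(hit_readm || hit_death)
  }
  oedema <- FALSE
  cause <- ""
  if (!is.na(first_t) && first_t <= index_discharge + 90) {
    cls <- classify_readmission_cause(split_codes(readm$icd10[1]))
    oedema <- cls$pulmonary_oedema_any
    cause <- paste(cls$categories, collapse = ",")
  }
  out$outcome_pulm_oedema_90 <- as.integer(oedema)
  out$readmission_cause <- cause
  out$first_readmission_time <- first_t
  out
}

#' Assemble the analysis cohort from linked source tables
#'
#' For every patient: detects AKI episodes from the creatinine series,
#' selects the index admission (first with AKI, else last in the study
#' year), derives the candidate predictors (AKI stage of the episode
#' overlapping the index admission, prior episodes 91-1095 days before the
#' index episode, baseline eGFR by CKD-EPI, the >20% discharge non-recovery
#' flag, admission context, and Quan-mapped Charlson comorbidity flags from
#' the 5 prior years), and defines the composite outcomes.  Patients on
#' chronic RRT before index, without a study-year admission, or without a
#' computable baseline (when `missing_baseline = "exclude"`) are excluded
#' with a reason.
#'
#' @param labs Data.frame `patient_id`, `time`, `creatinine`.
#' @param admissions Data.frame `patient_id`, `admit_time`,
#'   `discharge_time`, `emergency`, `medical_ward`, `icu`, `icd10`.
#' @param deaths Data.frame `patient_id`, `death_time`.
#' @param demographics Data.frame `patient_id`, `age`, `male`,
#'   `residential_care`, `deprived`, `rural`, optional `chronic_rrt`.
#' @param study_window Study-year window in days (default `c(0, 365)`).
#' @param horizons Outcome horizons (default `c(30, 60, 90)`).
#' @param merge_same_day_transfers Merge admissions that start on a
#'   previous discharge day into one stay (default TRUE).
#' @param missing_baseline `"exclude"` (default) or `"flag"`: disposition
#'   for patients with no test in either baseline window (flagged patients
#'   keep `baseline_egfr = NA`).
#' @return List of class `aki_cohort`: `cohort` (one row per included
#'   patient), `exclusions` (`patient_id`, `reason`), `episodes` (all
#'   detected episodes).
#' @export
build_cohort <- function(labs, admissions, deaths, demographics,
                         study_window = c(0, 365), horizons = c(30, 60, 90),
                         merge_same_day_transfers = TRUE,
                         missing_baseline = c("exclude", "flag")) {
  missing_baseline <- match.arg(missing_baseline)
  episodes_all <- detect_episodes_all(labs)
  labs_dt <- data.table::as.data.table(labs)
  data.table::setkey(labs_dt, patient_id, time)
  adm_dt <- data.table::as.data.table(admissions)
  death_lookup <- stats::setNames(deaths$death_time, deaths$patient_id)
  qmap <- quan_charlson_map()
  rows <- list()
  excl <- list()
  for (k in seq_len(nrow(demographics))) {
    dem <- demographics[k, ]
    pid <- dem$patient_id
    if (!is.null(dem$chronic_rrt) && isTRUE(dem$chronic_rrt == 1)) {
      excl[[length(excl) + 1]] <- data.frame(patient_id = pid, reason = "chronic_rrt")
      next
    }
    adm_p <- as.data.frame(adm_dt[list(pid), on = "patient_id", nomatch = NULL])
    if (merge_same_day_transfers && nrow(adm_p) > 1) adm_p <- merge_transfers(adm_p)
    ep_p <- episodes_all[episodes_all$patient_id == pid, , drop = FALSE]
    index <- select_index_admission(adm_p, ep_p, study_window)
    if (is.null(index)) {
      excl[[length(excl) + 1]] <- data.frame(patient_id = pid,
                                             reason = "no_study_year_admission")
      next
    }
    lab_p <- labs_dt[list(pid), on = "patient_id", nomatch = NULL]
    t_lab <- lab_p$time; v_lab <- lab_p$creatinine

    ep_index <- ep_p[ep_p$start_time <= index$discharge_time &
                       ep_p$end_time >= index$admit_time, , drop = FALSE]
    has_aki <- nrow(ep_index) > 0
    aki_stage <- if (has_aki) max(ep_index$peak_stage) else 0L
    index_ref <- if (has_aki) min(ep_index$start_time) else index$admit_time
    if (has_aki) {
      baseline <- ep_index$baseline_used[which.min(ep_index$start_time)]
    } else {
      bl <- rolling_baseline(t_lab, v_lab, index$admit_time)
      baseline <- bl$baseline_value
    }
    if (is.na(baseline) && missing_baseline == "exclude") {
      excl[[length(excl) + 1]] <- data.frame(patient_id = pid,
                                             reason = "no_baseline")
      next
    }
    egfr <- if (is.na(baseline)) NA_real_ else
      ckd_epi_egfr(baseline, dem$age, female = dem$male == 0)

    in_adm <- t_lab >= index$admit_time & t_lab <= index$discharge_time
    discharge_creat <- if (any(in_adm)) v_lab[max(which(in_adm))] else NA_real_
    nonrec <- if (is.na(baseline) || is.na(discharge_creat)) 0L else
      as.integer(non_recovery_flag(discharge_creat, baseline))

    prior_ct <- count_prior_episodes(ep_p$start_time, index_ref)
    past_year <- sum(adm_p$admit_time >= index$admit_time - 365 &
                       adm_p$admit_time <= index$admit_time - 1)
    prior5y <- adm_p[adm_p$admit_time >= index$admit_time - 1825 &
                       adm_p$admit_time <= index$admit_time - 1, , drop = FALSE]
    codes5y <- unlist(lapply(prior5y$icd10, split_codes))
    comorb <- vapply(qmap, function(p)
      as.integer(length(codes5y) > 0 && matches_prefix(codes5y, p)), integer(1))

    later <- adm_p[adm_p$admit_time > index$discharge_time, , drop = FALSE]
    oc <- define_outcomes(index$discharge_time, later,
                          if (as.character(pid) %in% names(death_lookup))
                            death_lookup[[as.character(pid)]] else NA_real_,
                          horizons)
    rows[[length(rows) + 1]] <- data.frame(
      patient_id = pid, age = dem$age, male = dem$male,
      residential_care = dem$residential_care, deprived = dem$deprived,
      rural = dem$rural,
      adm_past_year = past_year,
      length_of_stay = index$discharge_time - index$admit_time,
      emergency = index$emergency, medical_ward = index$medical_ward,
      icu = index$icu,
      aki_stage = aki_stage, prior_aki_count = prior_ct,
      baseline_creatinine = baseline, baseline_egfr = egfr,
      nonrecovery = nonrec,
      t(comorb),
      oc[setdiff(names(oc), c("readmission_cause", "first_readmission_time"))],
      readmission_cause = oc$readmission_cause,
      stringsAsFactors = FALSE)
  }
  cohort <- if (length(rows)) as.data.frame(data.table::rbindlist(rows))
            else data.frame()
  exclusions <- if (length(excl)) as.data.frame(data.table::rbindlist(excl))
                else data.frame(patient_id = integer(0), reason = character(0))
  stopifnot(nrow(cohort) + nrow(exclusions) == nrow(demographics))
  structure(list(cohort = cohort, exclusions = exclusions,
                 episodes = episodes_all), class = "aki_cohort")
}

#' @export
print.aki_cohort <- function(x, ...) {
  cat(sprintf("Assembled cohort: %d patients included, %d excluded\n",
              nrow(x$cohort), nrow(x$exclusions)))
  if (nrow(x$exclusions))
    print(table(x$exclusions$reason))
  if (nrow(x$cohort))
    cat(sprintf("  AKI %d (%.1f%%); 90-day outcome %d (%.1f%%)\n",
                sum(x$cohort$aki_stage > 0),
                100 * mean(x$cohort$aki_stage > 0),
                sum(x$cohort$outcome_90), 100 * mean(x$cohort$outcome_90)))
  invisible(x)
}

#' Descriptive table with univariable odds ratios
#'
#' Counts and percentages of each binary candidate predictor by outcome
#' status, with the cross-product univariable odds ratio; continuous and
#' count predictors (age per 10 years, eGFR per 10 ml/min/1.73 m^2, prior
#' admissions and prior AKI per unit, length of stay per week) are
#' summarised by single-predictor logistic regression.
#'
#' @param cohort Cohort data.frame from [build_cohort()].
#' @param outcome Outcome column (default `"outcome_90"`).
#' @return Data.frame: predictor, events, nonevents (counts for binary
#'   rows), or, ci_low, ci_high.
#' @export
univariable_table <- function(cohort, outcome = "outcome_90") {
  y <- cohort[[outcome]]
  binary <- c("male", "residential_care", "deprived", "rural", "emergency",
              "medical_ward", "icu", "nonrecovery",
              names(quan_charlson_map()))
  rows <- list()
  for (v in binary) {
    a <- sum(cohort[[v]] == 1 & y == 1); b <- sum(cohort[[v]] == 1 & y == 0)
    c0 <- sum(cohort[[v]] == 0 & y == 1); d <- sum(cohort[[v]] == 0 & y == 0)
    or <- tryCatch(univariable_odds_ratio(a, b, c0, d),
                   error = function(e) list(or = NA, ci_low = NA, ci_high = NA))
    rows[[v]] <- data.frame(predictor = v, events = a, nonevents = b,
                            or = or$or, ci_low = or$ci_low, ci_high = or$ci_high)
  }
  for (s in 1:3) {
    a <- sum(cohort$aki_stage == s & y == 1)
    b <- sum(cohort$aki_stage == s & y == 0)
    c0 <- sum(cohort$aki_stage == 0 & y == 1)
    d <- sum(cohort$aki_stage == 0 & y == 0)
    or <- tryCatch(univariable_odds_ratio(a, b, c0, d),
                   error = function(e) list(or = NA, ci_low = NA, ci_high = NA))
    rows[[paste0("aki_stage", s)]] <- data.frame(
      predictor = paste0("aki_stage", s), events = a, nonevents = b,
      or = or$or, ci_low = or$ci_low, ci_high = or$ci_high)
  }
  cont <- list(age_per10 = (cohort$age) / 10,
               egfr_per10 = cohort$baseline_egfr / 10,
               adm_past_year = cohort$adm_past_year,
               prior_aki_count = cohort$prior_aki_count,
               los_per_week = cohort$length_of_stay / 7)
  for (v in names(cont)) {
    fit <- stats::glm(y ~ x, family = stats::binomial(),
                      data = data.frame(y = y, x = cont[[v]]))
    cf <- stats::coef(summary(fit))["x", ]
    rows[[v]] <- data.frame(predictor = v, events = NA, nonevents = NA,
                            or = exp(cf["Estimate"]),
                            ci_low = exp(cf["Estimate"] - 1.959964 * cf["Std. Error"]),
                            ci_high = exp(cf["Estimate"] + 1.959964 * cf["Std. Error"]))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
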