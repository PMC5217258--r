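#' @importFrom stats median
NULL

# KDIGO staging bands on the peak/baseline ratio, plus the absolute stage-3
# creatinine cut.  Ratio bands: [1.5, 2) -> 1, [2, 3) -> 2, >= 3 -> 3.
STAGE3_ABSOLUTE_UMOL <- 354
MGDL_TO_UMOL <- 88.4

#' Stage a creatinine value against a baseline
#'
#' Applies the KDIGO ratio bands to `value / baseline` and the absolute
#' stage-3 cut (creatinine >= 354 umol/L).  Returns 0 when the value does not
#' reach the stage-1 band.
#'
#' @param value Serum creatinine, umol/L.
#' @param baseline Reference (baseline) creatinine, umol/L.
#' @return Integer stage 0-3.
#' @export
kdigo_stage <- function(value, baseline) {
  stopifnot(all(value > 0), all(baseline > 0))
  ratio <- value / baseline
  stage <- ifelse(ratio >= 3, 3L, ifelse(ratio >= 2, 2L, ifelse(ratio >= 1.5, 1L, 0L)))
  stage <- ifelse(value >= STAGE3_ABSOLUTE_UMOL & stage >= 1L, 3L, stage)
  as.integer(stage)
}

#' Rolling baseline creatinine
#'
#' The baseline at query time `t` is the median of all creatinine values
#' measured 8-90 days before `t`; if that window holds no tests, the median
#' of values 91-365 days before `t`; otherwise the baseline is undefined.
#' Both windows are inclusive at both ends.
#'
#' @param times Numeric vector of test times in days, sorted increasing.
#' @param values Creatinine values (umol/L) aligned with `times`.
#' @param t Query time in days.
#' @return A list with `baseline_value` (NA when undefined), `window_used`
#'   (`"8-90"`, `"91-365"` or `"undefined"`) and `n_tests_in_window`.
#' @export
rolling_baseline <- function(times, values, t) {
  stopifnot(length(times) == length(values), !is.unsorted(times))
  in_w1 <- times >= t - 90 & times <= t - 8
  if (any(in_w1)) {
    return(list(baseline_value = median(values[in_w1]), window_used = "8-90",
                n_tests_in_window = sum(in_w1)))
  }
  in_w2 <- times >= t - 365 & times <= t - 91
  if (any(in_w2)) {
    return(list(baseline_value = median(values[in_w2]), window_used = "91-365",
                n_tests_in_window = sum(in_w2)))
  }
  list(baseline_value = NA_real_, window_used = "undefined", n_tests_in_window = 0L)
}

#' Detect and stage AKI episodes in one patient's creatinine series
#'
#' Implements the e-alert criteria: a test opens an episode when its value is
#' (i) >= 1.5 times the rolling baseline (median of tests 8-90 days ago, or
#' 91-365 days ago if none), (ii) >= 1.5 times the lowest creatinine within
#' the previous 7 days, or (iii) more than 26 umol/L above the lowest
#' creatinine within the previous 48 h.  The short-window lows are taken over
#' tests strictly before the current one.  An open episode is extended by
#' subsequent tests; it closes at the first test back at or below 1.2 times
#' the episode baseline, or 90 days after it started, whichever comes first.
#' The episode's stage is the highest KDIGO stage achieved relative to the
#' baseline identified when the episode opened (absolute-criterion triggers
#' with no ratio-band rise count as stage 1).  After closure the rolling
#' baseline is re-assessed from post-episode data, so later rises qualify as
#' recurrent episodes only if they again meet the criteria.
#'
#' @param times Test times in days (sorted increasing; ties keep input order).
#' @param values Creatinine values in umol/L, aligned with `times`.
#' @param patient_id Optional identifier copied into the result.
#' @return A data.frame with one row per episode: `patient_id`, `start_time`,
#'   `end_time`, `peak_stage`, `baseline_used`, `peak_value`, `trigger`.
#' @export
detect_episodes <- function(times, values, patient_id = NA) {
  stopifnot(length(times) == length(values))
  if (is.unsorted(times)) stop("creatinine series must be sorted by time")
  if (any(values <= 0)) stop("creatinine values must be positive")
  n <- length(times)
  eps <- list()
  in_ep <- FALSE
  ep_start <- ep_base <- ep_peak <- ep_stage <- ep_last <- ep_trigger <- NULL

  close_ep <- function(end_time) {
    # enforce a minimal 1-day duration so start < end always holds
    eps[[length(eps) + 1L]] <<- data.frame(
      patient_id = patient_id,
      start_time = ep_start,
      end_time = max(min(end_time, ep_start + 90), ep_start + 1),
      peak_stage = ep_stage,
      baseline_used = ep_base,
      peak_value = ep_peak,
      trigger = ep_trigger,
      stringsAsFactors = FALSE)
    in_ep <<- FALSE
  }

  for (i in seq_len(n)) {
    t <- times[i]; v <- values[i]
    if (in_ep && t > ep_start + 90) close_ep(ep_last)
    if (in_ep) {
      if (v <= 1.2 * ep_base) {
        close_ep(t)
      } else {
        st <- kdigo_stage(v, ep_base)
        if (v > ep_peak) ep_peak <- v
        if (st > ep_stage) ep_stage <- st
        ep_last <- t
        next
      }
    }
    if (!in_ep) {
      bl <- rolling_baseline(times, values, t)
      prior <- times < t
      low7 <- if (any(prior & times >= t - 7)) min(values[prior & times >= t - 7]) else NA_real_
      low48 <- if (any(prior & times >= t - 2)) min(values[prior & times >= t - 2]) else NA_real_
      trig <- NULL
      if (!is.na(bl$baseline_value) && v >= 1.5 * bl$baseline_value) {
        trig <- "ratio-vs-baseline"
      } else if (!is.na(low7) && v >= 1.5 * low7) {
        trig <- "ratio-vs-7day-low"
      } else if (!is.na(low48) && v - low48 > 26) {
        trig <- "absolute-48h-rise"
      }
      if (!is.null(trig)) {
        in_ep <- TRUE
        ep_start <- t
        ep_trigger <- trig
        ep_base <- if (!is.na(bl$baseline_value)) bl$baseline_value
                   else if (trig == "ratio-vs-7day-low") low7 else low48
        ep_peak <- v
        ep_last <- t
        ep_stage <- max(1L, kdigo_stage(v, ep_base))
      }
    }
  }
  if (in_ep) close_ep(ep_last)
  if (length(eps) == 0L) {
    return(data.frame(patient_id = patient_id[0], start_time = numeric(0),
                      end_time = numeric(0), peak_stage = integer(0),
                      baseline_used = numeric(0), peak_value = numeric(0),
                      trigger = character(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, eps)
}

#' Detect episodes for every patient in a long-format lab table
#'
#' @param labs A data.frame with columns `patient_id`, `time` (days) and
#'   `creatinine` (umol/L).
#' @return A data.frame of episodes across patients (see [detect_episodes()]).
#' @export
detect_episodes_all <- function(labs) {
  stopifnot(all(c("patient_id", "time", "creatinine") %in% names(labs)))
  dt <- data.table::as.data.table(labs)
  data.table::setkey(dt, patient_id, time)
  out <- dt[, detect_episodes(time, creatinine)[, -1, drop = FALSE],
            by = patient_id]
  as.data.frame(out)
}

#' Count prior AKI episodes
#'
#' Counts episodes whose start lies 91-1095 days before the index time
#' (inclusive window `[index_start - 1095, index_start - 91]`).
#'
#' @param episode_starts Numeric vector of episode start times (days).
#' @param index_start Start time (days) of the index episode or admission.
#' @return Integer count.
#' @export
count_prior_episodes <- function(episode_starts, index_start) {
  if (length(episode_starts) == 0L) return(0L)
  sum(episode_starts >= index_start - 1095 & episode_starts <= index_start - 91)
}

#' Non-recovery flag
#'
#' TRUE when discharge creatinine is more than 20% above baseline
#' (strictly greater than 1.2 times baseline).
#'
#' @param discharge_creatinine,baseline Creatinine values, umol/L.
#' @return Logical.
#' @export
non_recovery_flag <- function(discharge_creatinine, baseline) {
  if (any(discharge_creatinine <= 0) || any(baseline <= 0))
    stop("creatinine values must be positive")
  discharge_creatinine > 1.2 * baseline
}

#' CKD-EPI (2009) estimated glomerular filtration rate
#'
#' eGFR = 141 * min(Scr/kappa, 1)^alpha * max(Scr/kappa, 1)^-1.209 *
#' 0.993^age * 1.018 (if female), with kappa = 61.9 umol/L (0.7 mg/dL) and
#' alpha = -0.329 for women, kappa = 79.6 umol/L (0.9 mg/dL) and
#' alpha = -0.411 for men.  No race coefficient is applied by default; set
#' `black = TRUE` for the published 1.159 factor.
#'
#' @param creatinine Serum creatinine in umol/L (or mg/dL with
#'   `units = "mg/dL"`).
#' @param age Age in years (>= 18).
#' @param female Logical, TRUE for female.
#' @param black Logical, apply the 1.159 coefficient (default FALSE).
#' @param units `"umol/L"` (default) or `"mg/dL"`.
#' @return eGFR in ml/min/1.73 m^2.
#' @export
ckd_epi_egfr <- function(creatinine, age, female, black = FALSE,
                         units = c("umol/L", "mg/dL")) {
  units <- match.arg(units)
  if (any(creatinine <= 0)) stop("creatinine must be positive")
  scr <- if (units == "mg/dL") creatinine else creatinine / MGDL_TO_UMOL
  kappa <- ifelse(female, 0.7, 0.9)
  alpha <- ifelse(female, -0.329, -0.411)
  egfr <- 141 * pmin(scr / kappa, 1)^alpha * pmax(scr / kappa, 1)^(-1.209) *
    0.993^age * ifelse(female, 1.018, 1)
  if (isTRUE(black)) egfr <- egfr * 1.159
  egfr
}

#' Back-solve creatinine from a target CKD-EPI eGFR
#'
#' Closed-form inverse of [ckd_epi_egfr()] for a given age and sex; used by
#' the synthetic generator to place baseline creatinine inside an eGFR
#' category.
#'
#' @param egfr Target eGFR, ml/min/1.73 m^2.
#' @param age Age in years.
#' @param female Logical.
#' @return Creatinine in umol/L.
#' @export
creatinine_for_egfr <- function(egfr, age, female) {
  kappa <- ifelse(female, 0.7, 0.9)
  alpha <- ifelse(female, -0.329, -0.411)
  t <- egfr / (141 * 0.993^age * ifelse(female, 1.018, 1))
  scr <- ifelse(t <= 1, kappa * t^(-1 / 1.209), kappa * t^(1 / alpha))
  scr * MGDL_TO_UMOL
}
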