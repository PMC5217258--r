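# Candidate predictor terms and their encodings.
#
# Continuous age and eGFR enter with linear and quadratic terms, centred
# (age at 70 years, eGFR at 60 ml/min/1.73 m^2) and scaled per 10 units
# before squaring; centring improves conditioning and leaves fitted
# probabilities unchanged.  AKI stage enters as three dummies against "no
# AKI".  Multi-column groups (age pair, eGFR pair, AKI trio) are eliminated
# jointly during backward selection.

AGE_CENTER <- 70
EGFR_CENTER <- 60

#' Candidate predictor term specification
#'
#' One row per model column: `group` (terms sharing a group are tested and
#' eliminated jointly), `term` (column name in the design matrix) and
#' `label`.  The default set covers the 26 candidate predictors: age
#' (linear + quadratic), sex, residential care, deprivation, rurality,
#' admissions in the prior year, length of stay (per week), emergency /
#' medical-ward / intensive-care admission, AKI stage 1-3, prior AKI count,
#' baseline eGFR (linear + quadratic), non-recovery, and 12 comorbidities.
#'
#' @param subset One of `"full"`, `"admin_only"`, `"biochem_plus_age"`,
#'   `"age_alone"`, `"aki_alone"`.
#' @return A data.frame term specification.
#' @export
candidate_terms <- function(subset = c("full", "admin_only", "biochem_plus_age",
                                       "age_alone", "aki_alone")) {
  subset <- match.arg(subset)
  comorbidities <- c("cancer", "cardiac_failure", "cerebrovascular", "dementia",
                     "diabetes", "hemiplegia", "liver", "mi", "peptic_ulcer",
                     "pvd", "pulmonary", "rheumatic")
  spec <- rbind(
    data.frame(group = "age", term = c("age10c", "age10c_sq")),
    data.frame(group = "male", term = "male"),
    data.frame(group = "residential_care", term = "residential_care"),
    data.frame(group = "deprived", term = "deprived"),
    data.frame(group = "rural", term = "rural"),
    data.frame(group = "adm_past_year", term = "adm_past_year"),
    data.frame(group = "los_week", term = "los_week"),
    data.frame(group = "emergency", term = "emergency"),
    data.frame(group = "medical_ward", term = "medical_ward"),
    data.frame(group = "icu", term = "icu"),
    data.frame(group = "aki", term = c("aki1", "aki2", "aki3")),
    data.frame(group = "prior_aki", term = "prior_aki"),
    data.frame(group = "egfr", term = c("egfr10c", "egfr10c_sq")),
    data.frame(group = "nonrecovery", term = "nonrecovery"),
    data.frame(group = comorbidities, term = comorbidities)
  )
  keep <- switch(subset,
    full = spec$group,
    admin_only = setdiff(spec$group, c("aki", "prior_aki", "egfr", "nonrecovery")),
    biochem_plus_age = c("age", "aki", "prior_aki", "egfr", "nonrecovery"),
    age_alone = "age",
    aki_alone = "aki")
  spec[spec$group %in% keep, , drop = FALSE]
}

#' Build the design matrix for a term specification
#'
#' Derives encoded columns (centred/scaled age and eGFR with their squares,
#' AKI stage dummies, length of stay per week) from a cohort table and
#' returns the columns named in `terms`.
#'
#' @param rows Cohort data.frame (see [build_cohort()]).
#' @param terms Term specification from [candidate_terms()], or a character
#'   vector of term names.
#' @return Numeric matrix with one column per term (no intercept).
#' @export
term_matrix <- function(rows, terms = candidate_terms()) {
  term_names <- if (is.data.frame(terms)) terms$term else terms
  env <- as.list(rows)
  env$age10c <- (rows$age - AGE_CENTER) / 10
  env$age10c_sq <- env$age10c^2
  env$egfr10c <- (rows$baseline_egfr - EGFR_CENTER) / 10
  env$egfr10c_sq <- env$egfr10c^2
  env$aki1 <- as.numeric(rows$aki_stage == 1)
  env$aki2 <- as.numeric(rows$aki_stage == 2)
  env$aki3 <- as.numeric(rows$aki_stage == 3)
  if (!is.null(rows$length_of_stay)) env$los_week <- rows$length_of_stay / 7
  if (!is.null(rows$prior_aki_count)) env$prior_aki <- rows$prior_aki_count
  missing <- setdiff(term_names, names(env))
  if (length(missing))
    stop("cohort table lacks columns for terms: ", paste(missing, collapse = ", "))
  m <- vapply(term_names, function(nm) as.numeric(env[[nm]]), numeric(nrow(rows)))
  m <- matrix(m, nrow = nrow(rows), dimnames = list(NULL, term_names))
  m
}
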