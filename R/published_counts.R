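#' Published univariable two-by-two counts
#'
#' Aggregate counts reported for a regional Scottish hospital-discharge
#' cohort of 16453 patients (3065 with the 90-day readmission-or-death
#' outcome, 13388 without), bundled so the cross-product univariable odds
#' ratios can be recomputed.  For the AKI stage rows the unexposed group is
#' the no-AKI group (2154 events / 11676 non-events) rather than the
#' remaining cohort.
#'
#' @return Data.frame with `predictor`, `exposed_events`,
#'   `exposed_nonevents`, `unexposed_events`, `unexposed_nonevents` and
#'   `published_or`.
#' @export
published_univariable_counts <- function() {
  path <- system.file("extdata", "published_univariable_counts.csv",
                      package = "akiread", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
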