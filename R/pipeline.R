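# End-to-end pipeline: generate (or read) -> detect -> build -> model ->
# validate -> decision analysis.

#' Pipeline configuration
#'
#' Collects the settings for a full run.  Defaults mirror the analysis:
#' elimination threshold p >= 0.01, 500 bootstrap resamples, outcome
#' horizons 30/60/90 days, reclassification cutpoints 0.1/0.3 (main
#' outcome) and 0.01/0.1 (pulmonary-oedema outcome), and a decision-curve
#' grid of 0-0.6 with the pre-specified 0.2-0.4 band.
#'
#' @param synth A [synth_config()] for synthetic generation, or `NULL` to
#'   read CSVs from `input_dir`.
#' @param input_dir Directory of input CSVs when `synth` is `NULL`.
#' @param out_dir Output directory for the report bundle.
#' @param horizons Outcome horizons in days.
#' @param p_threshold Backward-elimination threshold.
#' @param B Bootstrap resamples for internal validation.
#' @param nri_cutpoints Risk-category cutpoints for the main-outcome NRI.
#' @param nri_cutpoints_oedema Cutpoints for the pulmonary-oedema NRI.
#' @param grid Decision-curve threshold grid.
#' @param band Pre-specified decision band.
#' @param seed Global seed.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(synth = synth_config(), input_dir = NULL,
                            out_dir = tempfile("akiread_run_"),
                            horizons = c(30, 60, 90), p_threshold = 0.01,
                            B = 500, nri_cutpoints = c(0.1, 0.3),
                            nri_cutpoints_oedema = c(0.01, 0.1),
                            grid = seq(0, 0.6, by = 0.01), band = c(0.2, 0.4),
                            seed = 1L) {
  cfg <- as.list(environment())
  stopifnot(p_threshold > 0, p_threshold <= 1, B >= 1,
            all(horizons %in% c(30, 60, 90)))
  if (is.null(synth) && is.null(input_dir))
    stop("either a synth config or an input_dir must be given")
  class(cfg) <- "pipeline_config"
  cfg
}

# stable short hash of a configuration for stamping artifacts
config_hash <- function(cfg) {
  s <- paste(deparse(cfg), collapse = "")
  h <- 5381
  for (ch in utf8ToInt(s)) h <- (h * 33 + ch) %% 2^31
  sprintf("%08x", h)
}

stage_msg <- function(stage, fmt, ...) {
  message(sprintf("[%s] %s: %s", format(Sys.time(), "%H:%M:%S"), stage,
                  sprintf(fmt, ...)))
}

#' Run the full analysis pipeline
#'
#' Generates or reads the source tables, detects AKI episodes, assembles
#' the cohort, produces the descriptive table with univariable odds
#' ratios, fits the six predictor-subset models per horizon, runs
#' bootstrap internal validation of the best stepwise model, decision
#' curve analysis across models, and NRI/IDI of the best stepwise model
#' against the administrative-data model.  All artifacts are written under
#' `config$out_dir` and stamped with the config hash and seed.
#'
#' @param config A [pipeline_config()].
#' @return List of class `aki_pipeline` with `cohort`, `models`,
#'   `c_statistics`, `validation`, `decision`, `reclassification`,
#'   `summary` (also written as `summary.json`).
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  t0 <- Sys.time()
  if (!is.null(config$synth)) {
    stage_msg("simulate", "generating %d synthetic patients",
              config$synth$n_patients)
    gen <- generate_cohort(config$synth)
    src <- gen[c("labs", "admissions", "deaths", "demographics")]
    write_cohort_csvs(gen, config$out_dir)
  } else {
    for (f in c("labs.csv", "admissions.csv", "deaths.csv", "demographics.csv")) {
      path <- file.path(config$input_dir, f)
      if (!file.exists(path)) stop("missing input file: ", path)
    }
    stage_msg("load", "reading CSVs from %s", config$input_dir)
    src <- read_cohort_csvs(config$input_dir)
    gen <- NULL
  }
  stage_msg("detect+build", "%d creatinine results, %d admissions",
            nrow(src$labs), nrow(src$admissions))
  built <- build_cohort(src$labs, src$admissions, src$deaths,
                        src$demographics, horizons = config$horizons)
  cohort <- built$cohort
  stage_msg("detect+build", "cohort %d included / %d excluded",
            nrow(cohort), nrow(built$exclusions))
  utils::write.csv(cohort, file.path(config$out_dir, "cohort.csv"),
                   row.names = FALSE)
  utils::write.csv(built$episodes, file.path(config$out_dir, "episodes.csv"),
                   row.names = FALSE)
  tab2 <- univariable_table(cohort)
  utils::write.csv(tab2, file.path(config$out_dir, "univariable.csv"),
                   row.names = FALSE)

  models_by_h <- list()
  for (h in config$horizons) {
    oc <- paste0("outcome_", h)
    stage_msg("fit", "predictor-subset models for %s", oc)
    models_by_h[[as.character(h)]] <-
      predictor_subset_models(cohort, config$p_threshold, oc)
  }
  main <- models_by_h[["90"]]
  or_tab <- odds_ratio_table(main$best_stepwise)
  utils::write.csv(or_tab, file.path(config$out_dir, "best_stepwise_model.csv"),
                   row.names = FALSE)
  write_model(main$best_stepwise,
              file.path(config$out_dir, "best_stepwise_model.txt"))

  scores <- lapply(main, predict_risk, rows = cohort)
  cstats <- vapply(scores, function(s)
    c_statistic(s, cohort$outcome_90)$c, numeric(1))
  utils::write.csv(data.frame(model = names(cstats), c_statistic = cstats),
                   file.path(config$out_dir, "model_comparison.csv"),
                   row.names = FALSE)

  stage_msg("validate", "bootstrap with B = %d", config$B)
  boot <- bootstrap_validate(cohort, candidate_terms(), B = config$B,
                             p_threshold = config$p_threshold,
                             outcome = "outcome_90", seed = config$seed)

  stage_msg("dca", "decision curves over %d thresholds", length(config$grid))
  dca <- decision_curve(scores[c("best_stepwise", "admin_only",
                                 "biochem_plus_age", "age_alone", "aki_alone")],
                        cohort$outcome_90, config$grid, config$band)
  utils::write.table(dca$curve, file.path(config$out_dir, "decision_curve.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  nri <- categorical_nri(scores$admin_only, scores$best_stepwise,
                         cohort$outcome_90, config$nri_cutpoints,
                         n_boot = 2000, seed = config$seed)
  idi_res <- idi(scores$admin_only, scores$best_stepwise, cohort$outcome_90,
                 n_boot = 2000, seed = config$seed)

  summary <- list(
    config_hash = config_hash(config), seed = config$seed,
    n_included = nrow(cohort), n_excluded = nrow(built$exclusions),
    exclusion_reasons = as.list(table(built$exclusions$reason)),
    event_rate_90 = mean(cohort$outcome_90),
    c_statistics = as.list(cstats),
    apparent_c = boot$apparent_c, optimism_c = boot$optimism_c,
    corrected_c = boot$corrected_c, corrected_slope = boot$corrected_slope,
    inclusion_frequency = as.list(boot$inclusion_frequency),
    nri_overall = nri$overall, idi = idi_res$idi,
    best_in_band = dca$best_in_band,
    runtime_s = as.numeric(difftime(Sys.time(), t0, units = "secs")))
  jsonlite::write_json(summary, file.path(config$out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  stage_msg("done", "bundle written to %s (%.1f s)", config$out_dir,
            summary$runtime_s)
  structure(list(cohort = built, models = models_by_h, c_statistics = cstats,
                 validation = boot, decision = dca,
                 reclassification = list(nri = nri, idi = idi_res),
                 summary = summary, config = config), class = "aki_pipeline")
}

#' @export
print.aki_pipeline <- function(x, ...) {
  cat("Pipeline run", x$summary$config_hash, "seed", x$summary$seed, "\n")
  cat(sprintf("  cohort %d, event rate %.3f\n", x$summary$n_included,
              x$summary$event_rate_90))
  cat("  C statistics:\n")
  print(round(unlist(x$summary$c_statistics), 3))
  cat(sprintf("  corrected C %.3f, corrected slope %.3f, NRI %+0.3f, IDI %+0.4f\n",
              x$summary$corrected_c, x$summary$corrected_slope,
              x$summary$nri_overall, x$summary$idi))
  invisible(x)
}
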