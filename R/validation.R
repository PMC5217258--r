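#' C statistic (ROC area) with DeLong 95% confidence interval
#'
#' Probability that a randomly chosen event receives a higher score than a
#' randomly chosen non-event, ties counted one half; the Wilcoxon / Mann-
#' Whitney estimator of the area under the ROC curve.  The variance is the
#' DeLong structural-components estimate.
#'
#' @param scores Numeric predictions (any monotone scale).
#' @param outcomes Binary outcomes (0/1 or logical).
#' @return List with `c`, `ci_low`, `ci_high`, `se`, `n_events`,
#'   `n_nonevents`.
#' @export
c_statistic <- function(scores, outcomes) {
  y <- as.numeric(outcomes)
  if (length(unique(y)) < 2) stop("both outcome classes must be present")
  pc <- delong_placements(scores, y)
  auc <- pc$auc
  v <- stats::var(pc$v10) / pc$m + stats::var(pc$v01) / pc$n
  se <- sqrt(v)
  list(c = auc,
       ci_low = max(0, auc - 1.959964 * se),
       ci_high = min(1, auc + 1.959964 * se),
       se = se, n_events = pc$m, n_nonevents = pc$n)
}

# DeLong placement values: v10[i] = P(score of event i > random non-event)
# with ties 1/2; v01[j] analogous for non-events.  Computed via midranks.
delong_placements <- function(scores, y) {
  ev <- scores[y == 1]; ne <- scores[y == 0]
  m <- length(ev); n <- length(ne)
  r_all <- rank(c(ev, ne), ties.method = "average")
  r_ev <- rank(ev, ties.method = "average")
  r_ne <- rank(ne, ties.method = "average")
  v10 <- (r_all[seq_len(m)] - r_ev) / n
  v01 <- 1 - (r_all[m + seq_len(n)] - r_ne) / m
  auc <- (sum(r_all[seq_len(m)]) - m * (m + 1) / 2) / (m * n)
  list(v10 = v10, v01 = v01, auc = auc, m = m, n = n)
}

#' Paired comparison of two C statistics (DeLong test)
#'
#' Tests the difference in ROC area between two models scored on the same
#' patients, accounting for the pairing via DeLong's structural components.
#'
#' @param scores_a,scores_b Paired prediction vectors.
#' @param outcomes Binary outcomes.
#' @return List with `auc_a`, `auc_b`, `diff`, `se`, `z`, `p` (two-sided).
#' @export
compare_auc <- function(scores_a, scores_b, outcomes) {
  if (length(scores_a) != length(scores_b))
    stop("score vectors must be paired (equal length)")
  y <- as.numeric(outcomes)
  pa <- delong_placements(scores_a, y)
  pb <- delong_placements(scores_b, y)
  s10 <- stats::cov(cbind(pa$v10, pb$v10))
  s01 <- stats::cov(cbind(pa$v01, pb$v01))
  s <- s10 / pa$m + s01 / pa$n
  v <- s[1, 1] + s[2, 2] - 2 * s[1, 2]
  d <- pa$auc - pb$auc
  if (v <= .Machine$double.eps) {
    z <- 0
    p <- 1
  } else {
    z <- d / sqrt(v)
    p <- 2 * stats::pnorm(-abs(z))
  }
  list(auc_a = pa$auc, auc_b = pb$auc, diff = d,
       se = sqrt(max(v, 0)), z = z, p = p)
}

#' Calibration table and calibration slope
#'
#' Groups patients into bins of increasing predicted risk (deciles by
#' default) and reports mean predicted vs mean observed risk per bin.  The
#' calibration slope is the coefficient obtained when the outcomes are refit
#' on the model's linear predictor alone; a slope below 1 indicates
#' overfitting.
#'
#' @param scores Predicted probabilities.
#' @param outcomes Binary outcomes.
#' @param n_bins Number of risk bins (default 10).
#' @return List with `table` (bin, n, mean_predicted, observed_rate) and
#'   `slope`.
#' @export
calibration <- function(scores, outcomes, n_bins = 10) {
  stopifnot(n_bins >= 2)
  y <- as.numeric(outcomes)
  if (length(unique(scores)) < 2) stop("constant scores cannot be calibrated")
  br <- unique(stats::quantile(scores, probs = seq(0, 1, length.out = n_bins + 1)))
  bin <- cut(scores, breaks = br, include.lowest = TRUE, labels = FALSE)
  tab <- data.frame(
    bin = sort(unique(bin)),
    n = as.vector(table(bin)),
    mean_predicted = tapply(scores, bin, mean),
    observed_rate = tapply(y, bin, mean),
    row.names = NULL)
  lp <- stats::qlogis(pmin(pmax(scores, 1e-12), 1 - 1e-12))
  slope_fit <- stats::glm(y ~ lp, family = stats::binomial())
  list(table = tab, slope = unname(stats::coef(slope_fit)["lp"]))
}

#' Hosmer-Lemeshow goodness of fit, with sample-size standardisation
#'
#' Classic Hosmer-Lemeshow chi-square over risk-decile groups.  Because the
#' statistic grows with n and rejects trivially in large samples, a
#' standardised version is also reported: the statistic is recomputed on
#' `n_rep` random subsamples of `reference_n` patients and averaged.  With
#' `reference_n` equal to the full sample the standardised statistic equals
#' the raw one.
#'
#' @param scores Predicted probabilities.
#' @param outcomes Binary outcomes.
#' @param n_groups Number of risk groups (default 10); empty groups are
#'   merged with a warning.
#' @param df Degrees of freedom for the p-value, `n_groups - 2` by default
#'   (the development-sample convention).
#' @param reference_n Subsample size for standardisation (default: full n).
#' @param n_rep Subsamples to average (default 100).
#' @param seed Seed for the subsampling.
#' @return List with `statistic`, `p`, `df`, `standardized_statistic`,
#'   `standardized_p`, `reference_n`.
#' @export
hosmer_lemeshow_std <- function(scores, outcomes, n_groups = 10, df = NULL,
                                reference_n = NULL, n_rep = 100, seed = 1L) {
  stopifnot(n_groups >= 3)
  y <- as.numeric(outcomes)
  n <- length(y)
  if (is.null(reference_n)) reference_n <- n
  hl_stat <- function(sc, yy) {
    br <- unique(stats::quantile(sc, probs = seq(0, 1, length.out = n_groups + 1)))
    if (length(br) < n_groups + 1)
      warning("tied score quantiles: groups merged (", length(br) - 1, " used)")
    g <- cut(sc, breaks = br, include.lowest = TRUE, labels = FALSE)
    o <- tapply(yy, g, sum)
    e <- tapply(sc, g, sum)
    nn <- tapply(yy, g, length)
    pbar <- e / nn
    sum((o - e)^2 / (nn * pbar * (1 - pbar)))
  }
  stat <- hl_stat(scores, y)
  if (is.null(df)) df <- n_groups - 2
  if (reference_n >= n) {
    std <- stat
  } else {
    rng <- local_rng(seed)
    vals <- vapply(seq_len(n_rep), function(i) {
      idx <- sample.int(n, reference_n)
      hl_stat(scores[idx], y[idx])
    }, numeric(1))
    restore_rng(rng)
    std <- mean(vals)
  }
  list(statistic = stat, p = stats::pchisq(stat, df, lower.tail = FALSE),
       df = df, standardized_statistic = std,
       standardized_p = stats::pchisq(std, df, lower.tail = FALSE),
       reference_n = reference_n)
}

#' Bootstrap internal validation with optimism correction
#'
#' Draws `B` bootstrap resamples of the cohort rows, reruns the full
#' backward-selection modelling process in each, and measures each
#' bootstrap model both in its own resample and in the original data.  The
#' mean difference of the two C statistics is the optimism, subtracted from
#' the apparent C to give the corrected C; calibration slopes of the
#' bootstrap models evaluated in the original data give the corrected
#' slope.  Group inclusion frequencies over the resamples quantify
#' selection stability.
#'
#' @param rows Cohort data.frame.
#' @param terms Candidate term specification.
#' @param B Number of bootstrap resamples (the analysis default is 500).
#' @param p_threshold Elimination threshold (default 0.01).
#' @param outcome Outcome column name.
#' @param seed Integer seed; one RNG substream per resample so results are
#'   reproducible and insensitive to skipped resamples.
#' @return List of class `aki_boot`: `apparent_c`, `optimism_c`,
#'   `corrected_c`, `apparent_slope`, `corrected_slope`, `slope_interval`
#'   (2.5/97.5 percentiles over resamples), `inclusion_frequency`,
#'   `B`, `B_used`, `seed`.
#' @export
bootstrap_validate <- function(rows, terms = candidate_terms(), B = 500,
                               p_threshold = 0.01, outcome = "outcome_90",
                               seed = 1L) {
  stopifnot(B >= 1)
  sel <- backward_eliminate(rows, terms, p_threshold, outcome)
  apparent_scores <- predict_risk(sel$fit, rows)
  y <- rows[[outcome]]
  apparent_c <- c_statistic(apparent_scores, y)$c
  apparent_slope <- tryCatch(calibration(apparent_scores, y)$slope,
                             error = function(e) NA_real_)
  groups <- unique(terms$group)
  incl <- stats::setNames(numeric(length(groups)), groups)
  opt <- slopes <- numeric(0)
  n <- nrow(rows)
  used <- 0L
  for (b in seq_len(B)) {
    rng <- local_rng(substream_seed(seed, b))
    idx <- sample.int(n, n, replace = TRUE)
    restore_rng(rng)
    boot_rows <- rows[idx, , drop = FALSE]
    if (length(unique(boot_rows[[outcome]])) < 2) next
    fit_b <- tryCatch(backward_eliminate(boot_rows, terms, p_threshold, outcome)$fit,
                      error = function(e) NULL)
    if (is.null(fit_b)) next
    used <- used + 1L
    kept <- unique(fit_b$terms$group)
    incl[kept] <- incl[kept] + 1
    c_boot <- c_statistic(predict_risk(fit_b, boot_rows), boot_rows[[outcome]])$c
    sc_orig <- predict_risk(fit_b, rows)
    c_orig <- c_statistic(sc_orig, y)$c
    opt <- c(opt, c_boot - c_orig)
    slopes <- c(slopes, tryCatch(calibration(sc_orig, y)$slope,
                                 error = function(e) NA_real_))
  }
  if (used == 0L) stop("every bootstrap resample failed or was single-class")
  optimism_c <- mean(opt)
  slopes <- slopes[is.finite(slopes)]
  structure(list(
    apparent_c = apparent_c,
    optimism_c = optimism_c,
    corrected_c = apparent_c - optimism_c,
    apparent_slope = apparent_slope,
    corrected_slope = mean(slopes),
    slope_interval = unname(stats::quantile(slopes, c(0.025, 0.975))),
    inclusion_frequency = incl / used,
    B = B, B_used = used, seed = seed,
    model = sel$fit), class = "aki_boot")
}

#' @export
print.aki_boot <- function(x, ...) {
  cat(sprintf("Bootstrap validation (B = %d, %d usable resamples)\n", x$B, x$B_used))
  cat(sprintf("  apparent C  %.4f   optimism %.4f   corrected C %.4f\n",
              x$apparent_c, x$optimism_c, x$corrected_c))
  cat(sprintf("  corrected calibration slope %.3f (%.3f-%.3f)\n",
              x$corrected_slope, x$slope_interval[1], x$slope_interval[2]))
  cat("  inclusion frequencies:\n")
  print(round(sort(x$inclusion_frequency, decreasing = TRUE), 3))
  invisible(x)
}
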