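#' Net benefit of a prediction rule at a threshold probability
#'
#' Net benefit = (TP/n) - (FP/n) * t/(1 - t), where a patient is classified
#' positive when their score is at or above the threshold t.  The second
#' term converts false positives into true-positive equivalents at the
#' odds of the threshold probability.
#'
#' @param scores Predicted probabilities.
#' @param outcomes Binary outcomes.
#' @param threshold Threshold probability in `[0, 1)`.
#' @return Signed net benefit per patient.
#' @export
net_benefit <- function(scores, outcomes, threshold) {
  if (any(threshold >= 1) || any(threshold < 0))
    stop("threshold must lie in [0, 1)")
  y <- as.numeric(outcomes)
  n <- length(y)
  vapply(threshold, function(t) {
    pos <- scores >= t
    tp <- sum(pos & y == 1)
    fp <- sum(pos & y == 0)
    tp / n - fp / n * t / (1 - t)
  }, numeric(1))
}

#' Decision curve for a set of models
#'
#' Net benefit across a grid of threshold probabilities for each supplied
#' score set, together with the treat-all strategy (everyone classified
#' positive) and treat-none (net benefit identically zero).
#'
#' @param score_sets Named list of predicted-probability vectors, one per
#'   model.
#' @param outcomes Binary outcomes.
#' @param grid Threshold grid (default 0 to 0.6 in steps of 0.01).
#' @param band Threshold band over which the best model is reported
#'   (default the pre-specified 0.2-0.4).
#' @return An object of class `aki_dca`: list with `curve` (data.frame:
#'   threshold, one net-benefit column per strategy), `band`, `best_in_band`.
#' @export
decision_curve <- function(score_sets, outcomes, grid = seq(0, 0.6, by = 0.01),
                           band = c(0.2, 0.4)) {
  stopifnot(is.list(score_sets), length(score_sets) > 0,
            all(grid >= 0), all(grid <= 0.99))
  if (is.null(names(score_sets)) || any(names(score_sets) == ""))
    stop("score_sets must be a named list")
  y <- as.numeric(outcomes)
  curve <- data.frame(threshold = grid)
  for (nm in names(score_sets))
    curve[[nm]] <- net_benefit(score_sets[[nm]], y, grid)
  curve[["treat_all"]] <- net_benefit(rep(1, length(y)), y, grid)
  curve[["treat_none"]] <- 0
  in_band <- curve$threshold >= band[1] & curve$threshold <= band[2]
  strategies <- setdiff(names(curve), "threshold")
  mean_nb <- vapply(strategies, function(s) mean(curve[[s]][in_band]), numeric(1))
  structure(list(curve = curve, band = band,
                 best_in_band = names(which.max(mean_nb))),
            class = "aki_dca")
}

#' @export
print.aki_dca <- function(x, ...) {
  cat(sprintf("Decision curve over thresholds %.2f-%.2f (%d points)\n",
              min(x$curve$threshold), max(x$curve$threshold), nrow(x$curve)))
  cat(sprintf("  highest mean net benefit in band %.2f-%.2f: %s\n",
              x$band[1], x$band[2], x$best_in_band))
  invisible(x)
}

#' Plot a decision curve
#'
#' Base-graphics plot of net benefit against threshold probability for each
#' strategy, with the pre-specified decision band shaded.
#'
#' @param x An `aki_dca` object.
#' @param ... Passed to `matplot`.
#' @export
plot.aki_dca <- function(x, ...) {
  strategies <- setdiff(names(x$curve), "threshold")
  m <- as.matrix(x$curve[strategies])
  graphics::matplot(x$curve$threshold, m, type = "l", lty = 1,
                    xlab = "Threshold probability", ylab = "Net benefit",
                    ylim = c(min(0, min(m)), max(m)), ...)
  graphics::rect(x$band[1], graphics::par("usr")[3], x$band[2],
                 graphics::par("usr")[4], col = grDevices::adjustcolor("grey", 0.2),
                 border = NA)
  graphics::abline(h = 0, col = "grey40", lty = 3)
  graphics::legend("topright", legend = strategies, col = seq_along(strategies),
                   lty = 1, bty = "n", cex = 0.8)
  invisible(x)
}

# risk category under two cutpoints: 1 = low [0,c1), 2 = medium [c1,c2),
# 3 = high [c2,1]; lower-inclusive boundaries.
risk_category <- function(scores, cutpoints) {
  findInterval(scores, c(cutpoints[1], cutpoints[2]), left.open = FALSE) + 1L
}

#' Categorical net reclassification improvement
#'
#' Compares risk categories (low/medium/high under two cutpoints) assigned
#' by an old and a new model.  Event NRI = (upward - downward moves) /
#' events among events; non-event NRI = (downward - upward moves) /
#' non-events among non-events; overall NRI is their sum.  Percentile
#' bootstrap intervals are computed over patient resamples.
#'
#' @param old_scores,new_scores Paired predicted probabilities.
#' @param outcomes Binary outcomes.
#' @param cutpoints Two increasing cutpoints in (0, 1); risk exactly at a
#'   cutpoint falls in the upper category.
#' @param n_boot Bootstrap resamples for the intervals (default 2000).
#' @param seed Seed for the bootstrap.
#' @return List with `overall`, `event`, `nonevent` point estimates,
#'   matching `*_ci` percentile intervals, `cutpoints`, `n_boot`.
#' @export
categorical_nri <- function(old_scores, new_scores, outcomes,
                            cutpoints = c(0.1, 0.3), n_boot = 2000, seed = 1L) {
  stopifnot(length(cutpoints) == 2, cutpoints[1] > 0,
            cutpoints[1] < cutpoints[2], cutpoints[2] < 1,
            length(old_scores) == length(new_scores))
  y <- as.numeric(outcomes)
  if (all(y == 1) || all(y == 0)) stop("both outcome classes must be present")
  point <- nri_components(old_scores, new_scores, y, cutpoints)
  boot <- matrix(NA_real_, nrow = n_boot, ncol = 3)
  n <- length(y)
  for (b in seq_len(n_boot)) {
    rng <- local_rng(substream_seed(seed, b, phase = 7L))
    idx <- sample.int(n, n, replace = TRUE)
    restore_rng(rng)
    if (length(unique(y[idx])) < 2) next
    cmp <- nri_components(old_scores[idx], new_scores[idx], y[idx], cutpoints)
    boot[b, ] <- c(cmp$overall, cmp$event, cmp$nonevent)
  }
  ci <- function(j) {
    v <- boot[, j]
    if (length(v) == 0 || all(is.na(v))) return(c(NA_real_, NA_real_))
    unname(stats::quantile(v, c(0.025, 0.975), na.rm = TRUE))
  }
  c(point, list(overall_ci = ci(1), event_ci = ci(2), nonevent_ci = ci(3),
                cutpoints = cutpoints, n_boot = n_boot))
}

nri_components <- function(old_scores, new_scores, y, cutpoints) {
  co <- risk_category(old_scores, cutpoints)
  cn <- risk_category(new_scores, cutpoints)
  up <- cn > co
  down <- cn < co
  ev <- y == 1
  event <- (sum(up[ev]) - sum(down[ev])) / sum(ev)
  nonevent <- (sum(down[!ev]) - sum(up[!ev])) / sum(!ev)
  list(overall = event + nonevent, event = event, nonevent = nonevent)
}

#' Integrated discrimination improvement
#'
#' IDI = (mean new - mean old score among events) + (mean old - mean new
#' score among non-events): the improvement in discrimination slope when
#' moving from the old to the new model.  Percentile bootstrap interval.
#'
#' @inheritParams categorical_nri
#' @return List with `idi`, `idi_ci`, `n_boot`.
#' @export
idi <- function(old_scores, new_scores, outcomes, n_boot = 2000, seed = 1L) {
  stopifnot(length(old_scores) == length(new_scores))
  y <- as.numeric(outcomes)
  if (all(y == 1) || all(y == 0)) stop("both outcome classes must be present")
  point_fn <- function(o, nw, yy) {
    (mean(nw[yy == 1]) - mean(o[yy == 1])) + (mean(o[yy == 0]) - mean(nw[yy == 0]))
  }
  point <- point_fn(old_scores, new_scores, y)
  n <- length(y)
  boot <- rep(NA_real_, n_boot)
  for (b in seq_len(n_boot)) {
    rng <- local_rng(substream_seed(seed, b, phase = 11L))
    idx <- sample.int(n, n, replace = TRUE)
    restore_rng(rng)
    if (length(unique(y[idx])) < 2) next
    boot[b] <- point_fn(old_scores[idx], new_scores[idx], y[idx])
  }
  idi_ci <- if (n_boot == 0 || all(is.na(boot))) c(NA_real_, NA_real_)
            else unname(stats::quantile(boot, c(0.025, 0.975), na.rm = TRUE))
  list(idi = point, idi_ci = idi_ci, n_boot = n_boot)
}
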