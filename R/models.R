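#' Univariable odds ratio from a two-by-two table
#'
#' Cross-product odds ratio with a Wald 95% confidence interval on the log
#' scale; identical to the exponentiated coefficient of a single-predictor
#' logistic regression.
#'
#' @param exposed_events,exposed_nonevents,unexposed_events,unexposed_nonevents
#'   Cell counts.
#' @param continuity Add 0.5 to every cell when any cell is zero
#'   (off by default; zero cells otherwise give an error).
#' @return List with `or`, `ci_low`, `ci_high`, `log_or`, `se`.
#' @export
univariable_odds_ratio <- function(exposed_events, exposed_nonevents,
                                   unexposed_events, unexposed_nonevents,
                                   continuity = FALSE) {
  cells <- c(exposed_events, exposed_nonevents, unexposed_events, unexposed_nonevents)
  if (any(cells < 0)) stop("counts must be non-negative")
  if (any(cells == 0)) {
    if (!continuity) stop("zero cell; set continuity = TRUE for the 0.5 correction")
    cells <- cells + 0.5
  }
  a <- cells[1]; b <- cells[2]; c <- cells[3]; d <- cells[4]
  log_or <- log(a * d / (b * c))
  se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  list(or = exp(log_or),
       ci_low = exp(log_or - 1.959964 * se),
       ci_high = exp(log_or + 1.959964 * se),
       log_or = log_or, se = se)
}

#' Fit a logistic regression for a set of candidate terms
#'
#' Maximum-likelihood fit via `stats::glm`.  Perfect or quasi-perfect
#' separation is detected (fitted probabilities collapsing to 0/1 or
#' exploding coefficients) and reported as an error rather than returned as
#' a spurious fit.
#'
#' @param rows Cohort data.frame with an outcome column.
#' @param terms Term specification (see [candidate_terms()]); may be empty
#'   for an intercept-only model.
#' @param outcome Name of the binary outcome column (default `"outcome_90"`).
#' @return An object of class `aki_fit`: list with `coefficients`, `se`,
#'   `vcov`, `terms` (specification), `outcome`, `loglik`, `n`, `converged`,
#'   and the underlying `glm` fit.
#' @export
fit_logistic <- function(rows, terms = candidate_terms(), outcome = "outcome_90") {
  y <- rows[[outcome]]
  if (is.null(y)) stop("outcome column not found: ", outcome)
  y <- as.numeric(y)
  if (length(unique(y)) < 2) stop("need at least one event and one non-event")
  spec <- if (is.data.frame(terms)) terms else data.frame(group = terms, term = terms)
  if (nrow(spec) > 0) {
    x <- cbind(`(Intercept)` = 1, term_matrix(rows, spec))
  } else {
    x <- matrix(1, nrow = length(y), dimnames = list(NULL, "(Intercept)"))
  }
  fit <- suppressWarnings(stats::glm.fit(x, y, family = stats::binomial(),
                                         control = stats::glm.control(maxit = 50)))
  cf <- fit$coefficients
  if (anyNA(cf)) stop("collinear terms produced aliased coefficients")
  mu <- fit$fitted.values
  if (max(abs(cf)) > 15 || any(mu > 1 - 1e-10) || any(mu < 1e-10))
    stop("(quasi-)perfect separation detected: coefficients diverge")
  if (!fit$converged)
    stop("IRLS failed to converge after ", fit$iter, " iterations")
  w <- fit$weights                      # IRLS weights mu * (1 - mu)
  vc <- chol2inv(chol(crossprod(x * sqrt(w))))
  dimnames(vc) <- list(colnames(x), colnames(x))
  loglik <- sum(y * log(mu) + (1 - y) * log1p(-mu))
  structure(list(
    coefficients = cf,
    se = sqrt(diag(vc)),
    vcov = vc,
    terms = spec,
    outcome = outcome,
    loglik = loglik,
    n = length(y),
    converged = fit$converged,
    fitted = mu), class = "aki_fit")
}

#' @export
print.aki_fit <- function(x, ...) {
  cat("Logistic model for", x$outcome, "(n =", x$n, ")\n")
  or <- exp(x$coefficients)
  lo <- exp(x$coefficients - 1.959964 * x$se)
  hi <- exp(x$coefficients + 1.959964 * x$se)
  p <- 2 * stats::pnorm(-abs(x$coefficients / x$se))
  print(round(data.frame(OR = or, ci_low = lo, ci_high = hi, p = p), 4))
  invisible(x)
}

#' Odds-ratio table for a fitted model
#'
#' @param fit An `aki_fit`.
#' @return Data.frame with term, OR, 95% CI and two-sided Wald p-value.
#' @export
odds_ratio_table <- function(fit) {
  z <- fit$coefficients / fit$se
  data.frame(term = names(fit$coefficients),
             or = exp(fit$coefficients),
             ci_low = exp(fit$coefficients - 1.959964 * fit$se),
             ci_high = exp(fit$coefficients + 1.959964 * fit$se),
             p = 2 * stats::pnorm(-abs(z)),
             row.names = NULL)
}

# p-value for one term-group in a fitted model: two-sided Wald for single
# columns, likelihood-ratio (refit without the group) for multi-column
# groups.  Returns the p-value and the log-likelihood drop of removing the
# group (used for deterministic tie-breaking).
group_pvalue <- function(rows, fit, group) {
  spec <- fit$terms
  cols <- spec$term[spec$group == group]
  if (length(cols) == 1L) {
    z <- fit$coefficients[cols] / fit$se[cols]
    p <- 2 * stats::pnorm(-abs(z))
    reduced <- NULL
    dll <- abs(z) / 2  # monotone proxy; exact drop computed only on ties
  } else {
    reduced <- fit_logistic(rows, spec[spec$group != group, , drop = FALSE], fit$outcome)
    lr <- 2 * (fit$loglik - reduced$loglik)
    p <- stats::pchisq(max(lr, 0), df = length(cols), lower.tail = FALSE)
    dll <- fit$loglik - reduced$loglik
  }
  list(p = unname(p), dloglik = unname(dll))
}

#' Backward elimination of predictor groups
#'
#' Starting from a fit of all candidate terms, repeatedly removes the
#' term-group with the largest p-value at or above `p_threshold` and refits,
#' until every remaining group is significant below the threshold.  Groups
#' with several columns (AKI stage trio, age and eGFR linear+quadratic
#' pairs) are tested jointly by likelihood ratio; single columns by
#' two-sided Wald.  Ties on p-value are broken by dropping the group whose
#' removal costs the least log-likelihood.
#'
#' @param rows Cohort data.frame.
#' @param terms Candidate term specification.
#' @param p_threshold Elimination threshold; groups with p >= this are
#'   candidates for removal (default 0.01).
#' @param outcome Outcome column name.
#' @return List with `fit` (final `aki_fit`) and `trace` (data.frame of
#'   dropped groups with their p-values, in drop order).
#' @export
backward_eliminate <- function(rows, terms = candidate_terms(),
                               p_threshold = 0.01, outcome = "outcome_90") {
  stopifnot(p_threshold > 0, p_threshold <= 1)
  spec <- terms
  trace <- data.frame(step = integer(0), group = character(0), p = numeric(0))
  fit <- fit_logistic(rows, spec, outcome)
  step <- 0L
  repeat {
    groups <- unique(spec$group)
    if (length(groups) == 0L) break
    stats_by_group <- lapply(groups, function(g) group_pvalue(rows, fit, g))
    p <- vapply(stats_by_group, `[[`, numeric(1), "p")
    removable <- which(p >= p_threshold)
    if (length(removable) == 0L) break
    worst <- removable[p[removable] == max(p[removable])]
    if (length(worst) > 1L) {
      dll <- vapply(stats_by_group[worst], `[[`, numeric(1), "dloglik")
      worst <- worst[which.min(dll)]
    }
    step <- step + 1L
    trace <- rbind(trace, data.frame(step = step, group = groups[worst],
                                     p = p[worst]))
    spec <- spec[spec$group != groups[worst], , drop = FALSE]
    fit <- fit_logistic(rows, spec, outcome)
  }
  list(fit = fit, trace = trace)
}

#' Fit the named predictor-subset models
#'
#' Produces the model set compared in the analysis: the full model (all
#' candidate predictors, no selection), the best stepwise model (backward
#' elimination from all candidates), and stepwise models restricted to
#' administrative data only, renal biochemistry plus age, age alone, and
#' AKI alone.
#'
#' @param rows Cohort data.frame.
#' @param p_threshold Elimination threshold (default 0.01).
#' @param outcome Outcome column name.
#' @return Named list of `aki_fit` objects: `full`, `best_stepwise`,
#'   `admin_only`, `biochem_plus_age`, `age_alone`, `aki_alone`.
#' @export
predictor_subset_models <- function(rows, p_threshold = 0.01,
                                    outcome = "outcome_90") {
  out <- list(full = fit_logistic(rows, candidate_terms("full"), outcome))
  for (s in c("best_stepwise", "admin_only", "biochem_plus_age",
              "age_alone", "aki_alone")) {
    subset <- if (s == "best_stepwise") "full" else s
    out[[s]] <- backward_eliminate(rows, candidate_terms(subset),
                                   p_threshold, outcome)$fit
  }
  out
}

#' Predicted risk from a fitted model
#'
#' @param fit An `aki_fit`.
#' @param rows Cohort rows supplying every model term.
#' @return Predicted probabilities in (0, 1).
#' @export
predict_risk <- function(fit, rows) {
  stats::plogis(linear_predictor(fit, rows))
}

#' Linear predictor (log-odds scale) from a fitted model
#'
#' @inheritParams predict_risk
#' @return Numeric vector of log-odds.
#' @export
linear_predictor <- function(fit, rows) {
  cf <- fit$coefficients
  lp <- rep(cf[["(Intercept)"]], nrow(rows))
  if (nrow(fit$terms) > 0) {
    x <- term_matrix(rows, fit$terms)
    lp <- lp + drop(x %*% cf[colnames(x)])
  }
  unname(lp)
}

#' Serialize a fitted model to a plain-text key-value file
#'
#' Writes one `term<TAB>coefficient<TAB>se` line per term at full double
#' precision so predictions reproduce bit-for-bit.
#'
#' @param fit An `aki_fit`.
#' @param path Output file path.
#' @export
write_model <- function(fit, path) {
  df <- data.frame(term = names(fit$coefficients),
                   coefficient = sprintf("%.17g", fit$coefficients),
                   se = sprintf("%.17g", fit$se))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a model written by [write_model()]
#'
#' @param path File path.
#' @param outcome Outcome label to attach.
#' @return An `aki_fit`-like object usable with [predict_risk()].
#' @export
read_model <- function(path, outcome = "outcome_90") {
  df <- utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  cf <- as.numeric(df$coefficient)
  names(cf) <- df$term
  terms <- df$term[df$term != "(Intercept)"]
  structure(list(coefficients = cf, se = as.numeric(df$se),
                 terms = data.frame(group = terms, term = terms),
                 outcome = outcome, n = NA_integer_, converged = TRUE),
            class = "aki_fit")
}
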