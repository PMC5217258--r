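test_that("univariable odds ratios reproduce cross-product arithmetic", {
  or <- univariable_odds_ratio(277, 471, 2788, 12917)
  expect_equal(or$or, 277 * 12917 / (471 * 2788), tolerance = 1e-12)
  expect_equal(round(or$or, 2), 2.72)
  expect_equal(univariable_odds_ratio(50, 50, 50, 50)$or, 1)
  # AKI stage 3 against the no-AKI reference group
  expect_equal(round(univariable_odds_ratio(150, 181, 2154, 11676)$or, 2), 4.49)
  expect_error(univariable_odds_ratio(0, 10, 10, 10), "zero cell")
  expect_equal(univariable_odds_ratio(0, 10, 10, 10, continuity = TRUE)$or,
               0.5 * 10.5 / (10.5 * 10.5))
})

test_that("logistic fit matches the closed-form odds ratio for one binary predictor", {
  counts <- c(a = 277, b = 471, c = 2788, d = 12917)
  rows <- data.frame(
    x = rep(c(1, 1, 0, 0), counts),
    outcome_90 = rep(c(1, 0, 1, 0), counts))
  fit <- fit_logistic(rows, "x")
  expect_equal(exp(fit$coefficients[["x"]]),
               univariable_odds_ratio(277, 471, 2788, 12917)$or,
               tolerance = 1e-6)
  # intercept-only model recovers logit of the event fraction
  fit0 <- fit_logistic(rows, character(0))
  expect_equal(fit0$coefficients[["(Intercept)"]],
               qlogis(mean(rows$outcome_90)), tolerance = 1e-8)
  # predictor identical to outcome: separation must be reported
  rows$sep <- rows$outcome_90
  expect_error(fit_logistic(rows, "sep"), "separation")
})

test_that("fitted covariance is symmetric positive definite and predictions lie in (0,1)", {
  d <- small_truth_cohort(n = 1200, seed = 61)
  fit <- fit_logistic(d$rows, candidate_terms("biochem_plus_age"))
  expect_equal(fit$vcov, t(fit$vcov), tolerance = 1e-12)
  expect_true(all(eigen(fit$vcov, symmetric = TRUE, only.values = TRUE)$values > 0))
  pr <- predict_risk(fit, d$rows)
  expect_true(all(pr > 0 & pr < 1))
})

test_that("backward elimination reaches a fixed point and is deterministic", {
  d <- small_truth_cohort(n = 3000, seed = 71)
  res <- backward_eliminate(d$rows, candidate_terms("biochem_plus_age"),
                            p_threshold = 0.05)
  # every surviving group is significant below threshold
  for (g in unique(res$fit$terms$group)) {
    p <- akiread:::group_pvalue(d$rows, res$fit, g)$p
    expect_lt(p, 0.05)
  }
  # no eliminated p-value below threshold at its elimination step
  if (nrow(res$trace)) expect_true(all(res$trace$p >= 0.05))
  res2 <- backward_eliminate(d$rows, candidate_terms("biochem_plus_age"),
                             p_threshold = 0.05)
  expect_identical(res$trace, res2$trace)
  expect_identical(res$fit$coefficients, res2$fit$coefficients)
  # threshold of 1 keeps the full candidate set (p-values never reach 1)
  res_all <- backward_eliminate(d$rows, candidate_terms("aki_alone"),
                                p_threshold = 1)
  expect_equal(nrow(res_all$trace), 0L)
})

test_that("a null predictor is eliminated and a real effect retained across seeds", {
  keep_true <- 0; drop_null <- 0
  n_seeds <- 20
  for (s in seq_len(n_seeds)) {
    set.seed(300 + s)
    n <- 1500
    rows <- data.frame(x_true = rnorm(n), x_null = rnorm(n))
    rows$outcome_90 <- rbinom(n, 1, plogis(-1 + 0.8 * rows$x_true))
    res <- backward_eliminate(rows,
                              data.frame(group = c("x_true", "x_null"),
                                         term = c("x_true", "x_null")),
                              p_threshold = 0.01)
    kept <- unique(res$fit$terms$group)
    if ("x_true" %in% kept) keep_true <- keep_true + 1
    if (!"x_null" %in% kept) drop_null <- drop_null + 1
  }
  expect_gte(keep_true / n_seeds, 0.95)
  expect_gte(drop_null / n_seeds, 0.95)
})

test_that("predictor subset models use their candidate lists", {
  d <- small_truth_cohort(n = 4000, seed = 81)
  models <- predictor_subset_models(d$rows, p_threshold = 0.05)
  expect_setequal(names(models), c("full", "best_stepwise", "admin_only",
                                   "biochem_plus_age", "age_alone", "aki_alone"))
  expect_equal(unique(models$aki_alone$terms$group), "aki")
  expect_false(any(c("aki", "prior_aki", "egfr", "nonrecovery") %in%
                     models$admin_only$terms$group))
  # full model contains every candidate group
  expect_setequal(unique(models$full$terms$group),
                  unique(candidate_terms("full")$group))
  # apparent discrimination of nested models is ordered
  y <- d$rows$outcome_90
  c_full <- c_statistic(predict_risk(models$full, d$rows), y)$c
  c_admin <- c_statistic(predict_risk(models$admin_only, d$rows), y)$c
  expect_gte(c_full, c_admin - 1e-9)
})

test_that("risk predictions respond monotonically to AKI stage", {
  d <- small_truth_cohort(n = 4000, seed = 91)
  fit <- fit_logistic(d$rows, candidate_terms("full"))
  row <- d$rows[7, , drop = FALSE]
  risks <- vapply(0:3, function(s) {
    row$aki_stage <- s
    predict_risk(fit, row)
  }, numeric(1))
  if (all(diff(fit$coefficients[c("aki1", "aki2", "aki3")]) > 0) &&
      fit$coefficients[["aki1"]] > 0) {
    expect_true(all(diff(risks) > 0))
  }
  # all-zero coefficients give probability one half
  fit0 <- fit
  fit0$coefficients[] <- 0
  expect_equal(unname(predict_risk(fit0, d$rows[1:5, ])), rep(0.5, 5))
})

test_that("model serialization round-trips predictions bit for bit", {
  d <- small_truth_cohort(n = 1500, seed = 55)
  fit <- fit_logistic(d$rows, candidate_terms("biochem_plus_age"))
  path <- withr::local_tempfile(fileext = ".txt")
  write_model(fit, path)
  back <- read_model(path)
  expect_identical(predict_risk(back, d$rows), predict_risk(fit, d$rows))
})
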