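test_that("rolling baseline uses the 8-90 day window, then 91-365, then undefined", {
  bl <- rolling_baseline(c(40, 70), c(78, 82), t = 100)
  expect_equal(bl$baseline_value, 80)
  expect_equal(bl$window_used, "8-90")
  expect_equal(bl$n_tests_in_window, 2L)

  bl2 <- rolling_baseline(c(-100), c(90), t = 100)  # only a test 200 days back
  expect_equal(bl2$baseline_value, 90)
  expect_equal(bl2$window_used, "91-365")

  bl3 <- rolling_baseline(c(96, 99), c(80, 82), t = 100)  # nothing before t-7
  expect_true(is.na(bl3$baseline_value))
  expect_equal(bl3$window_used, "undefined")

  # boundaries inclusive at both ends
  expect_equal(rolling_baseline(c(10), c(77), t = 100)$window_used, "8-90")
  expect_equal(rolling_baseline(c(92), c(77), t = 100)$window_used, "8-90")
})

test_that("episode detection fires on each criterion and stages by ratio bands", {
  s <- series_with_rise(baseline = 80, peak = 125)
  ep <- detect_episodes(s$times, s$values)
  expect_equal(nrow(ep), 1L)
  expect_equal(ep$peak_stage, 1L)          # 125/80 = 1.5625
  expect_equal(ep$trigger, "ratio-vs-baseline")

  # 48-h absolute rise: 60 -> 90 is a 30 umol/L rise (also a 1.5x rise
  # against the 7-day low, which takes precedence in the trigger label)
  ep2 <- detect_episodes(c(100, 101), c(60, 90))
  expect_equal(nrow(ep2), 1L)
  expect_equal(ep2$peak_stage, 1L)
  # 70 -> 97 rises 27 umol/L within 48 h without reaching any 1.5x ratio
  ep2b <- detect_episodes(c(100, 101), c(70, 97))
  expect_equal(nrow(ep2b), 1L)
  expect_equal(ep2b$peak_stage, 1L)
  expect_equal(ep2b$trigger, "absolute-48h-rise")

  # ratio >= 3 is stage 3
  s3 <- series_with_rise(baseline = 80, peak = 250)
  expect_equal(detect_episodes(s3$times, s3$values)$peak_stage, 3L)

  # ratio 1.44 stays below threshold
  s0 <- series_with_rise(baseline = 80, peak = 115)
  expect_equal(nrow(detect_episodes(s0$times, s0$values)), 0L)

  # absolute stage-3 cut at 354 umol/L upgrades a band-1 ratio
  sa <- series_with_rise(baseline = 220, peak = 360)  # ratio 1.64
  expect_equal(detect_episodes(sa$times, sa$values)$peak_stage, 3L)

  expect_error(detect_episodes(c(2, 1), c(80, 80)), "sorted")
})

test_that("episodes close on recovery, respect the 90-day cap, and re-baseline", {
  # recovery at day 104 (96 <= 1.2 * 80) closes the episode; a fresh rise
  # after re-baselining opens a second episode
  times <- c(10, 40, 70, 100, 102, 104, 150, 180, 210, 250)
  values <- c(80, 80, 80, 170, 130, 90, 80, 80, 80, 130)
  ep <- detect_episodes(times, values)
  expect_equal(nrow(ep), 2L)
  expect_equal(ep$end_time[1], 104)
  expect_equal(ep$peak_stage, c(2L, 1L))
  # no overlap, each at most 90 days
  expect_true(all(ep$end_time - ep$start_time <= 90))
  expect_true(all(ep$start_time[-1] >= ep$end_time[-nrow(ep)]))

  # persistent elevation: episode capped at 90 days, and the elevated
  # plateau becomes the new baseline (CKD progression, not recurrent AKI)
  times2 <- c(10, 40, 70, seq(100, 400, by = 30))
  values2 <- c(80, 80, 80, rep(130, 11))
  ep2 <- detect_episodes(times2, values2)
  expect_equal(nrow(ep2), 1L)
  expect_lte(ep2$end_time - ep2$start_time, 90)
})

test_that("detection is idempotent and ratio rules are scale invariant", {
  base_t <- setdiff(seq(5, 700, by = 45), 275:320)
  ep_t <- 300:310
  df <- rbind(data.frame(t = base_t, v = 100),
              data.frame(t = ep_t, v = 100 * c(1.55, 1.7, 2.4, 2.2, 1.9, 1.6,
                                               1.4, 1.15, 1.05, 1.0, 1.0)))
  df <- df[order(df$t), ]
  times <- df$t
  values <- df$v
  ep1 <- detect_episodes(times, values)
  ep2 <- detect_episodes(times, values)
  expect_identical(ep1, ep2)
  # scaling all values leaves ratio-triggered detection unchanged
  ep_scaled <- detect_episodes(times, values * 1.7)
  ratio_eps <- ep1[ep1$trigger != "absolute-48h-rise", ]
  ratio_scaled <- ep_scaled[ep_scaled$trigger != "absolute-48h-rise", ]
  expect_equal(ratio_scaled$start_time, ratio_eps$start_time)
  expect_equal(ratio_scaled$peak_stage[ratio_scaled$peak_value < 354],
               ratio_eps$peak_stage[ratio_scaled$peak_value < 354])
})

test_that("prior episode counting uses the 91-1095 day window", {
  expect_equal(count_prior_episodes(c(-100, -800) + 1000, 1000), 2L)
  expect_equal(count_prior_episodes(970, 1000), 0L)     # 30 days: too recent
  expect_equal(count_prior_episodes(numeric(0), 1000), 0L)
  # boundaries inclusive
  expect_equal(count_prior_episodes(1000 - 91, 1000), 1L)
  expect_equal(count_prior_episodes(1000 - 1095, 1000), 1L)
  expect_equal(count_prior_episodes(1000 - 90, 1000), 0L)
  expect_equal(count_prior_episodes(1000 - 1096, 1000), 0L)
})

test_that("non-recovery flag is a strict 20% worsening", {
  expect_true(non_recovery_flag(121, 100))
  expect_false(non_recovery_flag(120, 100))   # exactly 20%: not flagged
  expect_false(non_recovery_flag(90, 100))
  expect_error(non_recovery_flag(-1, 100), "positive")
})

test_that("CKD-EPI matches hand evaluation and is monotone", {
  # male, 74 years, creatinine 100 umol/L, evaluated by hand from the
  # 2009 equation: 141 * (1.1312/0.9)^-1.209 * 0.993^74
  expect_equal(ckd_epi_egfr(100, 74, female = FALSE), 63.59215, tolerance = 1e-6)
  # at creatinine exactly kappa both piecewise terms collapse to 1
  expect_equal(ckd_epi_egfr(0.7 * 88.4, 50, female = TRUE),
               141 * 0.993^50 * 1.018, tolerance = 1e-12)
  expect_equal(ckd_epi_egfr(0.9, 60, female = FALSE, units = "mg/dL"),
               141 * 0.993^60, tolerance = 1e-12)
  # monotone decreasing in creatinine and age
  cr <- seq(40, 400, by = 20)
  expect_true(all(diff(ckd_epi_egfr(cr, 70, FALSE)) < 0))
  expect_true(all(diff(ckd_epi_egfr(100, seq(20, 95, 5), TRUE)) < 0))
  expect_error(ckd_epi_egfr(-5, 70, TRUE), "positive")
})

test_that("back-solved creatinine inverts the eGFR equation", {
  for (g in c(22, 37, 52, 75, 95)) {
    expect_equal(ckd_epi_egfr(creatinine_for_egfr(g, 74, TRUE), 74, TRUE), g,
                 tolerance = 1e-9)
    expect_equal(ckd_epi_egfr(creatinine_for_egfr(g, 55, FALSE), 55, FALSE), g,
                 tolerance = 1e-9)
  }
})
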