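test_that("config validation rejects malformed fractions and sizes", {
  expect_error(synth_config(aki_prevalence = 1.2), "fractions")
  expect_error(synth_config(stage_mix = c(0.5, 0.4, 0.2)), "sum to 1")
  expect_error(synth_config(egfr_category_mix = c(1, 0, 0, 0.1)), "sum to 1")
  expect_error(synth_config(n_patients = 0), "n_patients")
})

test_that("generation is deterministic and patient streams are invariant to cohort size", {
  cfg <- synth_config(n_patients = 60, seed = 5)
  g1 <- generate_cohort(cfg)
  g2 <- generate_cohort(cfg)
  expect_identical(g1$labs, g2$labs)
  expect_identical(g1$admissions, g2$admissions)
  expect_identical(g1$truth, g2$truth)

  # patient i's records do not depend on how many other patients exist
  g_small <- generate_cohort(synth_config(n_patients = 25, seed = 5))
  expect_equal(g_small$labs[g_small$labs$patient_id <= 25, ],
               g1$labs[g1$labs$patient_id <= 25, ], ignore_attr = TRUE)
  expect_equal(g_small$truth$true_linear_predictor -
                 g_small$intercept,
               g1$truth$true_linear_predictor[1:25] - g1$intercept,
               tolerance = 1e-12)
})

test_that("zero AKI prevalence yields no injected episode windows", {
  cfg <- synth_config(n_patients = 40, aki_prevalence = 0, seed = 3)
  g <- generate_cohort(cfg)
  expect_true(all(g$truth$true_aki_stage == 0))
  # any remaining injected windows are prior episodes, before the index admit
  if (nrow(g$episode_windows) > 0) {
    a0 <- g$truth$admit_time[match(g$episode_windows$patient_id,
                                   g$truth$patient_id)]
    expect_true(all(g$episode_windows$start_day < a0))
  }
  cfg2 <- synth_config(n_patients = 40, aki_prevalence = 0, seed = 3,
                       prior_aki_dist = c(1, 0, 0))
  g2 <- generate_cohort(cfg2)
  expect_equal(nrow(g2$episode_windows), 0L)
  expect_true(all(g2$truth$true_prior_episode_count == 0))
})

test_that("injected trajectories sit in the requested stage band and recovery behaviour", {
  tr3 <- inject_aki_trajectory(80, 3, 0, 10, recovery = TRUE)
  expect_gte(max(tr3$value), 3 * 80)
  tr1 <- inject_aki_trajectory(80, 1, 0, 10, recovery = TRUE)
  expect_lte(tr1$value[nrow(tr1)], 1.2 * 80)
  expect_true(max(tr1$value) / 80 >= 1.5 && max(tr1$value) / 80 < 2)
  tr2n <- inject_aki_trajectory(100, 2, 0, 8, recovery = FALSE)
  expect_gt(tr2n$value[nrow(tr2n)], 1.2 * 100)
  expect_true(max(tr2n$value) / 100 >= 2 && max(tr2n$value) / 100 < 3)
  expect_error(inject_aki_trajectory(80, 4, 0, 10), "stage")
  expect_error(inject_aki_trajectory(80, 2, 0, 120), "duration")
})

test_that("noiseless injected trajectories round-trip through the detector", {
  for (stage in 1:3) for (rec in c(TRUE, FALSE)) {
    traj <- inject_aki_trajectory(90, stage, 100, 10, recovery = rec)
    times <- c(20, 50, 80, traj$day)
    values <- c(90, 90, 90, traj$value)
    ep <- detect_episodes(times, values)
    expect_equal(nrow(ep), 1L, info = sprintf("stage %d rec %s", stage, rec))
    expect_equal(ep$peak_stage, stage)
  }
})

test_that("realised mixes track configured probabilities within 3 binomial SEs", {
  n <- 4000
  cfg <- synth_config(n_patients = n, seed = 17)
  g <- generate_covariates(cfg)
  tr <- g$truth
  se3 <- function(p) 3 * sqrt(p * (1 - p) / n)
  expect_lt(abs(mean(tr$true_aki_stage > 0) - cfg$aki_prevalence),
            se3(cfg$aki_prevalence))
  for (nm in c("cancer", "diabetes", "pulmonary", "dementia")) {
    p <- cfg$comorbidity_prevalences[[nm]]
    expect_lt(abs(mean(tr[[nm]]) - p), se3(p))
  }
  p_rural <- cfg$prevalences[["rural"]]
  expect_lt(abs(mean(tr$rural) - p_rural), se3(p_rural))
  # realised event rate is calibrated to the target
  expect_lt(abs(mean(tr$true_outcome) - cfg$target_event_rate),
            se3(cfg$target_event_rate))
})

test_that("infeasible event-rate calibration is reported", {
  cfg <- synth_config(n_patients = 50, target_event_rate = 1, seed = 1)
  expect_error(generate_covariates(cfg), "infeasible calibration")
})

test_that("every patient has a pre-admission creatinine in the 8-365 day lookback", {
  g <- generate_cohort(synth_config(n_patients = 80, seed = 23))
  labs <- g$labs
  for (k in seq_len(nrow(g$truth))) {
    a0 <- g$truth$admit_time[k]
    pid <- g$truth$patient_id[k]
    t <- labs$time[labs$patient_id == pid]
    expect_true(any(t >= a0 - 365 & t <= a0 - 8), info = paste("patient", pid))
  }
})

test_that("cohort CSVs round-trip through write and read", {
  g <- generate_cohort(synth_config(n_patients = 20, seed = 9))
  dir <- withr::local_tempdir()
  write_cohort_csvs(g, dir)
  back <- read_cohort_csvs(dir)
  expect_equal(back$labs$time, g$labs$time)
  expect_equal(back$labs$creatinine, g$labs$creatinine)
  expect_equal(back$admissions$admit_time, g$admissions$admit_time)
  expect_equal(back$admissions$icd10, g$admissions$icd10)
  expect_equal(back$deaths$death_time, g$deaths$death_time)
})
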