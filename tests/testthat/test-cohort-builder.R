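adm_row <- function(admit, discharge, emergency = 1, icd10 = "",
                    medical_ward = 1, icu = 0, pid = 1) {
  data.frame(patient_id = pid, admit_time = admit, discharge_time = discharge,
             emergency = emergency, medical_ward = medical_ward, icu = icu,
             icd10 = icd10, stringsAsFactors = FALSE)
}

test_that("index admission is the first with AKI, else the last of the study year", {
  adm <- rbind(adm_row(60, 70), adm_row(180, 190))
  eps <- data.frame(start_time = c(61, 181), end_time = c(70, 190))
  idx <- select_index_admission(adm, eps)
  expect_equal(idx$admit_time, 60)      # March-like vs July-like: first AKI

  idx2 <- select_index_admission(adm, eps[0, ])
  expect_equal(idx2$admit_time, 180)    # no AKI: last admission wins

  # AKI overlapping only the later admission selects that one
  idx3 <- select_index_admission(adm, data.frame(start_time = 182, end_time = 200))
  expect_equal(idx3$admit_time, 180)

  expect_null(select_index_admission(adm_row(400, 410), eps[0, ]))
})

test_that("composite outcome windows are inclusive at the horizon and ignore electives", {
  later <- adm_row(189, 195, emergency = 1)
  oc <- define_outcomes(100, later, NA_real_)
  expect_equal(oc$outcome_90, 1L)       # day 89 after discharge
  expect_equal(oc$outcome_60, 0L)
  expect_equal(oc$outcome_30, 0L)

  # elective admission never counts
  oc2 <- define_outcomes(100, adm_row(110, 112, emergency = 0), NA_real_)
  expect_equal(oc2$outcome_90, 0L)

  # death at exactly discharge + 90 counts; at 91 it does not
  expect_equal(define_outcomes(100, adm_row(500, 501), 190)$outcome_90, 1L)
  expect_equal(define_outcomes(100, adm_row(500, 501), 191)$outcome_90, 0L)

  expect_error(define_outcomes(100, adm_row(90, 95), NA_real_), "data error")
})

test_that("outcomes are monotone in the horizon", {
  for (d in c(15, 45, 75)) {
    oc <- define_outcomes(0, adm_row(d, d + 2), NA_real_)
    expect_lte(oc$outcome_30, oc$outcome_60)
    expect_lte(oc$outcome_60, oc$outcome_90)
  }
})

test_that("readmission causes map ICD-10 ranges and the main-position rule", {
  cls <- classify_readmission_cause("I50.1")
  expect_equal(cls$categories, "pulmonary_oedema")
  expect_true(cls$pulmonary_oedema_main)

  expect_equal(classify_readmission_cause("J15.9")$categories,
               "lower_respiratory_infection")
  expect_equal(classify_readmission_cause("K52.9")$categories, character(0))
  expect_setequal(classify_readmission_cause(c("I21.0", "G45.9"))$categories,
                  c("acute_coronary_syndrome", "cerebrovascular"))
  # I50 in a secondary position: flagged as any-position but not main
  cls2 <- classify_readmission_cause(c("J18.0", "I50.0"))
  expect_true(cls2$pulmonary_oedema_any)
  expect_false(cls2$pulmonary_oedema_main)
  expect_equal(classify_readmission_cause(character(0))$categories, character(0))
  expect_error(classify_readmission_cause("notacode"), "notacode")
})

test_that("same-day transfers merge into a single stay", {
  g <- generate_cohort(synth_config(n_patients = 15, seed = 31))
  adm <- g$admissions
  pid <- adm$patient_id[1]
  one <- adm[adm$patient_id == pid, ][1, ]
  # split the stay into two contiguous records
  part1 <- one; part1$discharge_time <- one$admit_time + 1
  part2 <- one; part2$admit_time <- one$admit_time + 1
  adm2 <- rbind(adm[adm$patient_id != pid | adm$admit_time != one$admit_time, ],
                part1, part2)
  b1 <- build_cohort(g$labs, adm, g$deaths, g$demographics)
  b2 <- build_cohort(g$labs, adm2, g$deaths, g$demographics)
  expect_equal(b2$cohort$length_of_stay, b1$cohort$length_of_stay)
  expect_equal(b2$cohort$adm_past_year, b1$cohort$adm_past_year)
})

test_that("exclusions reconcile and chronic RRT patients are removed", {
  g <- generate_cohort(synth_config(n_patients = 120, seed = 13,
                                    prevalences = c(male = 0.434,
                                                    residential_care = 0.045,
                                                    deprived = 0.084, rural = 0.271,
                                                    emergency = 0.613,
                                                    medical_ward = 0.514,
                                                    icu = 0.028, chronic_rrt = 0.1)))
  b <- build_cohort(g$labs, g$admissions, g$deaths, g$demographics)
  expect_equal(nrow(b$cohort) + nrow(b$exclusions), nrow(g$demographics))
  n_rrt <- sum(g$demographics$chronic_rrt == 1)
  expect_equal(sum(b$exclusions$reason == "chronic_rrt"), n_rrt)
  expect_false(any(b$cohort$patient_id %in%
                     g$demographics$patient_id[g$demographics$chronic_rrt == 1]))
})

test_that("derived predictors agree with generator truth", {
  g <- generate_cohort(synth_config(n_patients = 400, seed = 47))
  b <- build_cohort(g$labs, g$admissions, g$deaths, g$demographics)
  m <- merge(b$cohort, g$truth, by = "patient_id", suffixes = c("_det", "_true"))
  expect_gte(mean(m$aki_stage_det == m$true_aki_stage), 0.99)
  expect_gte(mean(m$prior_aki_count_det == m$true_prior_episode_count), 0.99)
  expect_equal(m$adm_past_year_det, m$adm_past_year_true)
  expect_equal(m$outcome_90, m$true_outcome)
  expect_equal(m$cancer_det, m$cancer_true)
  expect_equal(m$diabetes_det, m$diabetes_true)
  # measured baseline eGFR is close to the generating value
  expect_lt(stats::median(abs(m$baseline_egfr_det - m$baseline_egfr_true)), 3)
  # comorbidity and outcome prevalences stay within 3 binomial SEs
  n <- nrow(m)
  se3 <- function(p) 3 * sqrt(p * (1 - p) / n)
  cfg <- g$config
  expect_lt(abs(mean(m$pulmonary_det) - cfg$comorbidity_prevalences[["pulmonary"]]),
            se3(cfg$comorbidity_prevalences[["pulmonary"]]))
})
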