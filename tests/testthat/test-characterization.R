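one_patient_cohort <- function(index_date = "2020-06-01") {
  data.frame(patient_id = "p1", index_date = d(index_date),
             crp_at_index = 2.5, si_at_index = TRUE,
             age_at_index = 70, sex = "male", low_ses = FALSE,
             death_date = as.Date(NA), stringsAsFactors = FALSE)
}

test_that("baseline extraction takes the most recent value strictly inside the window", {
  ir <- one_patient_cohort()
  idx <- ir$index_date
  labs <- data.frame(patient_id = "p1",
                     date = as.character(c(idx - 100, idx - 10, idx)),
                     analyte = "ldl_c", value = c(80, 95, 120))
  st <- make_store(labs = labs)
  bl <- extract_baseline(ir, st)
  # the on-index measurement is excluded ("before the index date" is strict)
  expect_equal(bl$ldl_c, 95)
  # only a measurement at index - 600 d: outside the 548-day window
  st2 <- make_store(labs = data.frame(patient_id = "p1",
                                      date = as.character(idx - 600),
                                      analyte = "ldl_c", value = 80))
  expect_true(is.na(extract_baseline(ir, st2)$ldl_c))
  # boundary: index - 548 d is inside
  st3 <- make_store(labs = data.frame(patient_id = "p1",
                                      date = as.character(idx - 548),
                                      analyte = "ldl_c", value = 80))
  expect_equal(extract_baseline(ir, st3)$ldl_c, 80)
})

test_that("baseline eGFR is computed from windowed creatinine", {
  ir <- one_patient_cohort()
  idx <- ir$index_date
  age <- as.numeric((idx - 30) - d("1950-06-15")) / 365.25
  scr <- inflaprev:::creatinine_for_egfr(55, age, "male")
  st <- make_store(labs = data.frame(patient_id = "p1",
                                     date = as.character(idx - 30),
                                     analyte = "serum_creatinine", value = scr))
  expect_equal(extract_baseline(ir, st)$egfr, 55, tolerance = 1e-6)
})

test_that("comorbidity history is strictly prior; cancer needs a >3-year-old code", {
  cls <- default_code_lists()
  ir <- one_patient_cohort()
  idx <- ir$index_date
  flags <- function(dx) comorbidity_history(ir, dx, cls)
  dx_after <- data.frame(patient_id = "p1", date = as.character(idx + 5),
                         icd9_code = "401.9")
  expect_false(flags(dx_after)$hypertension)
  dx_before <- data.frame(patient_id = "p1", date = as.character(idx - 5),
                          icd9_code = "401.9")
  expect_true(flags(dx_before)$hypertension)
  # malignancy 2 years before -> cancer flag FALSE; 4 years before -> TRUE
  expect_false(flags(data.frame(patient_id = "p1",
                                date = as.character(idx - 730),
                                icd9_code = "174.9"))$cancer)
  expect_true(flags(data.frame(patient_id = "p1",
                               date = as.character(idx - 1461),
                               icd9_code = "174.9"))$cancer)
  # NMSC never sets the cancer flag
  expect_false(flags(data.frame(patient_id = "p1",
                                date = as.character(idx - 1461),
                                icd9_code = "173.3"))$cancer)
})

test_that("drug exposure windows are half-open around the index day", {
  cls <- default_code_lists()
  ir <- one_patient_cohort()
  idx <- ir$index_date
  rx_at <- function(date) data.frame(patient_id = "p1",
                                     date = as.character(date),
                                     atc_code = "C10AA05")
  pre <- function(rx) drug_utilization(ir, rx, cls, classes = "statins",
                                       window = "pre")$statins
  post <- function(rx) drug_utilization(ir, rx, cls, classes = "statins",
                                        window = "post")$statins
  expect_true(pre(rx_at(idx - 365)))   # inclusive window start
  expect_true(pre(rx_at(idx - 1)))
  expect_false(pre(rx_at(idx)))        # index day in neither window
  expect_false(post(rx_at(idx)))
  expect_true(post(rx_at(idx + 1)))
  expect_true(post(rx_at(idx + 365)))
  expect_false(post(rx_at(idx + 366)))
  expect_false(pre(rx_at(idx - 366)))
})

test_that("windowed utilization equals a brute-force scan on synthetic data", {
  cls <- default_code_lists()
  sim <- simulate_cohort(generator_config(n_patients = 200, seed = 71))
  cohort <- build_cohort(sim$store, cls)
  ir <- cohort$index_records
  rx <- sim$store$prescriptions
  use <- drug_utilization(ir, rx, cls, classes = c("statins", "diuretics"))
  statin_codes <- concept_match(rx$atc_code, get_concept(cls, "statins"))
  for (j in seq_len(nrow(ir))) {
    dates <- rx$date[statin_codes & rx$patient_id == ir$patient_id[j]]
    brute <- any(dates >= ir$index_date[j] - 365 & dates < ir$index_date[j])
    expect_identical(use$statins[j], brute)
  }
})

test_that("group comparisons pick the declared test and degrade to NA", {
  set.seed(81)
  g <- rep(c("a", "b"), each = 50)
  x <- rnorm(100)
  expect_gt(compare_groups(c(x[1:50], x[1:50]), g, "continuous"), 0.99)
  # gross categorical imbalance: 900/100 vs 100/900
  xx <- c(rep(TRUE, 900), rep(FALSE, 100), rep(TRUE, 100), rep(FALSE, 900))
  gg <- rep(c("a", "b"), each = 1000)
  expect_lt(compare_groups(xx, gg, "categorical"), 0.001)
  # constant variable -> missing p
  expect_true(is.na(compare_groups(rep(1, 100), g, "continuous")))
  expect_true(is.na(compare_groups(rep(TRUE, 100), g, "categorical")))
  expect_true(is.na(compare_groups(rep(2.2, 100), g, "skewed")))
  p <- compare_groups(rnorm(100, mean = rep(c(0, 3), each = 50)), g, "continuous")
  expect_lt(p, 0.001)
})

test_that("characteristic tables cover the expected variables with conserved group sizes", {
  cls <- default_code_lists()
  sim <- simulate_cohort(generator_config(n_patients = 400, seed = 91))
  cohort <- build_cohort(sim$store, cls)
  ir <- cohort$index_records
  bl <- extract_baseline(ir, sim$store)
  cm <- comorbidity_history(ir, sim$store$diagnoses, cls)
  tab <- baseline_table(ir, bl, cm)
  need <- c("age_years", "female_sex", "current_smoker", "low_ses", "bmi",
            "sbp", "dbp", "crp", "egfr", "uacr", "haemoglobin",
            "total_cholesterol", "hdl_c", "ldl_c", "triglycerides",
            "ascvd_coronary", "ascvd_cerebrovascular", "ascvd_pad",
            "ascvd_other", "ckd", "diabetes", "hypertension", "copd",
            "dementia", "heart_failure", "atrial_fibrillation", "ibd",
            "rheumatoid_disease", "cns_inflammatory_disease",
            "liver_disease", "cancer")
  expect_true(all(need %in% tab$variable))
  nn <- attr(tab, "n")
  expect_equal(nn[["si"]] + nn[["non_si"]], nn[["overall"]])
  expect_equal(nn[["overall"]], nrow(ir))
  expect_true(all(tab$p_value >= 0 & tab$p_value <= 1, na.rm = TRUE))

  use <- drug_utilization(ir, sim$store$prescriptions, cls)
  ut <- utilization_table(ir, use)
  # every published drug class has a configured concept and a table row
  expect_setequal(ut$drug_class, inflaprev::DRUG_CLASS_CONCEPTS)
  expect_true(all(ut$overall_pct >= 0 & ut$overall_pct <= 100))
})
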