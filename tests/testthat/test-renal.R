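test_that("eGFR matches frozen reference values and the independent oracle", {
  expect_equal(egfr_ckd_epi_2021(1.0, 50, "male"), 91.69, tolerance = 0.001)
  # Scr/kappa = 1 makes both power terms unity
  expect_equal(egfr_ckd_epi_2021(0.7, 40, "female"), 112.06, tolerance = 0.001)
  for (scr in c(0.5, 0.9, 1.4, 3.2)) {
    for (age in c(20, 55, 85)) {
      for (sex in c("male", "female")) {
        expect_equal(egfr_ckd_epi_2021(scr, age, sex),
                     oracle_egfr(scr, age, sex), tolerance = 1e-10)
      }
    }
  }
  expect_error(egfr_ckd_epi_2021(0, 50, "male"), "positive")
})

test_that("eGFR is strictly decreasing in creatinine and age", {
  set.seed(3)
  scr <- runif(50, 0.4, 6); age <- runif(50, 18, 95)
  sex <- sample(c("male", "female"), 50, TRUE)
  expect_true(all(egfr_ckd_epi_2021(2 * scr, age, sex) <
                    egfr_ckd_epi_2021(scr, age, sex)))
  expect_true(all(egfr_ckd_epi_2021(scr, age + 5, sex) <
                    egfr_ckd_epi_2021(scr, age, sex)))
  expect_true(all(egfr_ckd_epi_2021(scr, age, sex) > 0))
})

test_that("creatinine inversion is the exact inverse of the 2021 equation", {
  set.seed(4)
  egfr <- runif(40, 5, 120); age <- runif(40, 18, 95)
  sex <- sample(c("male", "female"), 40, TRUE)
  scr <- inflaprev:::creatinine_for_egfr(egfr, age, sex)
  expect_equal(egfr_ckd_epi_2021(scr, age, sex), egfr, tolerance = 1e-8)
})

ref1 <- function(pid = "p1", date = "2020-06-01") {
  data.frame(patient_id = pid, reference_date = date)
}

ckd_store <- function(labs = NULL, diagnoses = NULL) {
  make_store(patients = data.frame(patient_id = "p1", sex = "male",
                                   birth_date = "1950-06-15"),
             labs = labs, diagnoses = diagnoses)
}

test_that("CKD classification fires on each criterion and boundary", {
  cls <- default_code_lists()
  scr_for <- function(egfr, date = "2020-01-01") {
    age <- as.numeric(d(date) - d("1950-06-15")) / 365.25
    data.frame(patient_id = "p1", date = date, analyte = "serum_creatinine",
               value = inflaprev:::creatinine_for_egfr(egfr, age, "male"))
  }
  # most recent prior eGFR 55 -> CKD, stage3
  r <- classify_ckd(ckd_store(labs = scr_for(55)), cls, ref1())
  expect_equal(as.character(r$ckd_status), "CKD")
  expect_equal(as.character(r$ckd_stage), "stage3")
  # eGFR 60 exactly: criterion is strict "<60"
  r <- classify_ckd(ckd_store(labs = scr_for(60)), cls, ref1())
  expect_equal(as.character(r$ckd_status), "no-CKD")
  # UACR exactly 30 mg/g: inclusive
  uacr <- data.frame(patient_id = "p1", date = "2020-01-01", analyte = "uacr",
                     value = 30)
  r <- classify_ckd(ckd_store(labs = rbind(scr_for(75), uacr)), cls, ref1())
  expect_equal(as.character(r$ckd_status), "CKD")
  expect_equal(as.character(r$ckd_stage), "stage1/2")
  # stage >= 3 diagnosis code alone -> CKD with unknown stage
  dx <- data.frame(patient_id = "p1", date = "2018-01-01", icd9_code = "585.4")
  r <- classify_ckd(ckd_store(diagnoses = dx), cls, ref1())
  expect_equal(as.character(r$ckd_status), "CKD")
  expect_equal(as.character(r$ckd_stage), "unknown")
  # no creatinine and no CKD diagnosis ever -> unknown
  r <- classify_ckd(ckd_store(), cls, ref1())
  expect_equal(as.character(r$ckd_status), "unknown")
  # measurements after the reference date do not count
  r <- classify_ckd(ckd_store(labs = scr_for(40, "2021-01-01")), cls, ref1())
  expect_equal(as.character(r$ckd_status), "no-CKD")
})

test_that("stage bands follow the half-open KDIGO convention", {
  cls <- default_code_lists()
  scr_for <- function(egfr) {
    age <- as.numeric(d("2020-01-01") - d("1950-06-15")) / 365.25
    data.frame(patient_id = "p1", date = "2020-01-01",
               analyte = "serum_creatinine",
               value = inflaprev:::creatinine_for_egfr(egfr, age, "male"))
  }
  stage_of <- function(egfr) {
    as.character(classify_ckd(ckd_store(labs = scr_for(egfr)), cls, ref1())$ckd_stage)
  }
  expect_equal(stage_of(10), "stage5")
  expect_equal(stage_of(14.9), "stage5")
  expect_equal(stage_of(15.1), "stage4")
  expect_equal(stage_of(29.9), "stage4")
  expect_equal(stage_of(30.1), "stage3")
  expect_equal(stage_of(59.9), "stage3")
  # exact band edges, evaluated without the creatinine round trip: ties
  # break to the less severe side of each half-open band
  mk <- function(egfr, uacr = NA_real_) {
    data.frame(latest_egfr = egfr, latest_uacr = uacr, ckd_status = "CKD")
  }
  expect_equal(as.character(assign_stage(mk(15))), "stage4")
  expect_equal(as.character(assign_stage(mk(30))), "stage3")
  expect_equal(as.character(assign_stage(mk(60, 45))), "stage1/2")
  expect_equal(as.character(assign_stage(mk(60, 29))), "unknown")
})

test_that("'any historical eGFR' rule is a config switch", {
  cls <- default_code_lists()
  age1 <- as.numeric(d("2019-01-01") - d("1950-06-15")) / 365.25
  age2 <- as.numeric(d("2020-01-01") - d("1950-06-15")) / 365.25
  labs <- data.frame(patient_id = "p1", date = c("2019-01-01", "2020-01-01"),
                     analyte = "serum_creatinine",
                     value = c(inflaprev:::creatinine_for_egfr(50, age1, "male"),
                               inflaprev:::creatinine_for_egfr(70, age2, "male")))
  latest <- classify_ckd(ckd_store(labs = labs), cls, ref1(date = "2020-06-01"))
  any_rule <- classify_ckd(ckd_store(labs = labs), cls, ref1(date = "2020-06-01"),
                           egfr_rule = "any")
  expect_equal(as.character(latest$ckd_status), "no-CKD")
  expect_equal(as.character(any_rule$ckd_status), "CKD")
})

test_that("assign_stage rejects non-CKD rows and agrees with classify_ckd", {
  cls <- default_code_lists()
  sim <- simulate_cohort(generator_config(n_patients = 150, seed = 8))
  fa <- first_ascvd(sim$store$diagnoses, cls)
  refs <- data.frame(patient_id = fa$patient_id, reference_date = fa$first_ascvd_date + 200)
  r <- classify_ckd(sim$store, cls, refs)
  # status partition covers the cohort
  expect_equal(sum(table(r$ckd_status)), nrow(refs))
  ckd_rows <- r[r$ckd_status == "CKD", ]
  expect_equal(as.character(assign_stage(ckd_rows)), as.character(ckd_rows$ckd_stage))
  expect_equal(sum(table(ckd_rows$ckd_stage)), nrow(ckd_rows))
  expect_error(assign_stage(r), "CKD")
})

test_that("classification recovers the generator's true CKD stratum", {
  sim <- simulate_cohort(generator_config(n_patients = 2000, seed = 12))
  cls <- default_code_lists()
  truth <- sim$truth$patients
  refs <- data.frame(patient_id = truth$patient_id,
                     reference_date = truth$first_ascvd_date + 400)
  r <- classify_ckd(sim$store, cls, refs)
  called_ckd <- r$ckd_status == "CKD"
  sens <- mean(called_ckd[truth$ckd])
  spec <- mean(!called_ckd[!truth$ckd])
  # imperfect only through measurement sparsity/noise at the band edges
  expect_gt(sens, 0.85)
  expect_gt(spec, 0.93)
  # true unknowns (no renal measurements, no CKD code) get no status
  expect_true(all(r$ckd_status[truth$no_renal_data] == "unknown"))
})
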