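# Seeded synthetic-cohort generator with exported ground truth.
#
# Emulates the statistical structure the phenotyping pipeline assumes:
# sparse, irregular CRP sampling over the study window; log-normal CRP with
# stratum-specific medians; infection episodes that jointly emit an
# antibiotic prescription and inflate any concurrent CRP above the acute
# cap; immunosuppressant users; cancer diagnoses; CKD induced
# mechanistically through creatinine/UACR values (so renal classification
# is exercised end-to-end, never via a label); and an exponential mortality
# process. Every stochastic choice flows from the single seed, so a fixed
# configuration reproduces byte-identical tables.

#' Build a validated generator configuration
#'
#' Defaults describe a realistic ASCVD primary-care cohort: age ~ 71 +/- 12
#' at cohort entry, 57% male, 32% with a true CKD stratum, CRP log-normal
#' with stratum medians 2.9 (CKD) / 2.2 (no CKD) mg/L and marginal log-sd
#' 1.03 (the log-sd implied by an interquartile range of 1.2-4.8 around a
#' median of 2.4). Baseline (non-infection) CRP is truncated at the acute
#' cap: values above 20 mg/L arise only from infection episodes, making the
#' infection rule testable against truth flags.
#'
#' @param n_patients Number of patients (> 0).
#' @param seed Integer RNG seed.
#' @param study_start,study_end Study window (ISO dates).
#' @param p_male Probability of male sex.
#' @param age_mean,age_sd Age at first ASCVD diagnosis, years.
#' @param p_ckd Probability of the true CKD stratum.
#' @param ckd_stage_probs Stage mix within CKD
#'   (`stage3`, `stage4`, `stage5`, `stage1/2`).
#' @param crp_log_median Named mg/L medians, `c(ckd = , non_ckd = )`.
#' @param crp_log_sigma Marginal log-scale SD of baseline CRP.
#' @param crp_patient_intercept_sd Between-patient log-scale SD (within-
#'   patient SD is reduced so the marginal SD stays `crp_log_sigma`); an
#'   assumption, as the source data carry no stated autocorrelation.
#' @param crp_rate_per_year Post-diagnosis CRP testing rate, tests/year.
#' @param pre_ascvd_crp_rate Pre-diagnosis CRP testing rate, tests/year.
#' @param crp_cap Acute-phase cap, mg/L.
#' @param infection_rate_per_year Infection episodes per patient-year.
#' @param p_immunosuppressant_user,p_cancer,p_nmsc,p_chronic_infection
#'   Per-patient probabilities.
#' @param annual_mortality Annual death probability after cohort entry.
#' @param p_ckd_dx_code Probability a true stage >= 3 patient also carries a
#'   CKD diagnosis code.
#' @param p_no_renal_data Fraction of non-CKD patients with no creatinine
#'   and no CKD code (true "unknown" status).
#' @param creatinine_rate_per_year,uacr_rate_per_year,lab_rate_per_year,vital_rate_per_year
#'   Measurement sampling rates per year.
#' @param egfr_noise_sd Log-scale measurement noise on eGFR trajectories.
#' @param comorbidity_prev Named per-patient probabilities of comorbidity
#'   diagnoses.
#' @param drug_class_prev Named per-patient probabilities of background
#'   drug-class exposure (antibiotics/antivirals/immunosuppressants are
#'   driven by their own processes, never listed here).
#' @param p_minimum_earnings Probability of the minimum-earnings SES flag.
#' @return A validated list of class `generator_config`.
#' @export
generator_config <- function(
    n_patients = 1000,
    seed = 1L,
    study_start = "2014-01-01",
    study_end = "2023-07-31",
    p_male = 0.57,
    age_mean = 71, age_sd = 12,
    p_ckd = 0.32,
    ckd_stage_probs = c("stage3" = 0.711, "stage4" = 0.098,
                        "stage5" = 0.011, "stage1/2" = 0.18),
    crp_log_median = c(ckd = 2.9, non_ckd = 2.2),
    crp_log_sigma = 1.03,
    crp_patient_intercept_sd = 0.3,
    crp_rate_per_year = 0.16,
    pre_ascvd_crp_rate = 0.05,
    crp_cap = 20,
    infection_rate_per_year = 0.3,
    p_immunosuppressant_user = 0.02,
    p_cancer = 0.08,
    p_nmsc = 0.02,
    p_chronic_infection = 0.02,
    annual_mortality = 0.05,
    p_ckd_dx_code = 0.5,
    p_no_renal_data = 0.09,
    creatinine_rate_per_year = 0.8,
    uacr_rate_per_year = 0.3,
    lab_rate_per_year = 0.7,
    vital_rate_per_year = 0.7,
    egfr_noise_sd = 0.04,
    comorbidity_prev = c(diabetes = 0.34, hypertension = 0.66, copd = 0.30,
                         dementia = 0.05, heart_failure = 0.10,
                         atrial_fibrillation = 0.13, ibd = 0.008,
                         rheumatoid_disease = 0.18,
                         cns_inflammatory_disease = 0.002,
                         liver_disease = 0.05),
    drug_class_prev = c(statins = 0.69, aspirin = 0.54,
                        antiplatelet_agents = 0.25, anticoagulants = 0.14,
                        nsaids = 0.31, acei_arb = 0.60, mra = 0.05,
                        beta_blockers = 0.42, diuretics = 0.25,
                        calcium_channel_blockers = 0.20,
                        glucose_lowering = 0.29, sglt2_inhibitors = 0.04,
                        glp1_receptor_agonists = 0.016,
                        corticosteroids = 0.06, antimycotics = 0.01,
                        ezetimibe = 0.03, pcsk9_inhibitors = 0.003,
                        omega3 = 0.002, fibrates_resins_nicotinic = 0.05,
                        other_bp_medications = 0.04, colchicine = 0.017),
    p_minimum_earnings = 0.05) {
  cfg <- as.list(environment())
  if (!is.numeric(n_patients) || n_patients < 1) stop("n_patients must be positive")
  cfg$n_patients <- as.integer(n_patients)
  cfg$study_start <- as.Date(study_start)
  cfg$study_end <- as.Date(study_end)
  if (cfg$study_start >= cfg$study_end) stop("study_start must precede study_end")
  probs <- c(p_male, p_ckd, p_immunosuppressant_user, p_cancer, p_nmsc,
             p_chronic_infection, annual_mortality, p_ckd_dx_code,
             p_no_renal_data, p_minimum_earnings, ckd_stage_probs,
             comorbidity_prev, drug_class_prev)
  if (any(probs < 0 | probs > 1)) stop("all probabilities must lie in [0, 1]")
  rates <- c(crp_rate_per_year, pre_ascvd_crp_rate, infection_rate_per_year,
             creatinine_rate_per_year, uacr_rate_per_year, lab_rate_per_year,
             vital_rate_per_year)
  if (any(rates < 0)) stop("all rates must be non-negative")
  if (crp_log_sigma < crp_patient_intercept_sd) {
    stop("crp_log_sigma must be >= crp_patient_intercept_sd")
  }
  if (abs(sum(ckd_stage_probs) - 1) > 1e-8) stop("ckd_stage_probs must sum to 1")
  structure(cfg, class = "generator_config")
}

# truncated log-normal via inverse CDF (upper truncation at `cap`)
rlnorm_trunc <- function(n, meanlog, sdlog, cap) {
  u <- stats::runif(n) * stats::plnorm(cap, meanlog, sdlog)
  stats::qlnorm(u, meanlog, sdlog)
}

# uniform integer day offsets in [0, span]; span may be a vector
runif_days <- function(n, span) as.integer(floor(stats::runif(n) * (span + 1)))

GEN_CODES <- list(
  coronary = c("410.9", "411.1", "413.9", "414.0"),
  cerebrovascular = c("433.1", "434.9", "435.9", "438.0"),
  pad = c("440.2", "443.9"),
  other = c("440.9", "441.4", "444.2"),
  chronic_infection = c("042", "070.54", "011.9"),
  malignancy = c("153.9", "162.9", "174.9", "185"),
  nmsc = "173.3",
  antibiotic = c("J01CA04", "J01DD04", "J01MA02", "J05AB01"),
  immunosuppressant = c("L04AA06", "L04AX03"),
  ckd_stage_dx = c("stage3" = "585.3", "stage4" = "585.4", "stage5" = "585.5"),
  comorbidity = c(diabetes = "250.00", hypertension = "401.9", copd = "496",
                  dementia = "290.0", heart_failure = "428.0",
                  atrial_fibrillation = "427.31", ibd = "555.9",
                  rheumatoid_disease = "714.0",
                  cns_inflammatory_disease = "340", liver_disease = "571.9"),
  drug_class = c(statins = "C10AA05", aspirin = "B01AC06",
                 antiplatelet_agents = "B01AC04", anticoagulants = "B01AF01",
                 nsaids = "M01AE01", acei_arb = "C09AA02", mra = "C03DA01",
                 beta_blockers = "C07AB07", diuretics = "C03CA01",
                 calcium_channel_blockers = "C08CA01",
                 glucose_lowering = "A10BA02", sglt2_inhibitors = "A10BK03",
                 glp1_receptor_agonists = "A10BJ06",
                 corticosteroids = "H02AB06", antimycotics = "J02AC01",
                 ezetimibe = "C10AX09", pcsk9_inhibitors = "C10AX13",
                 omega3 = "C10AX06", fibrates_resins_nicotinic = "C10AB05",
                 other_bp_medications = "C02AC01", colchicine = "M04AC01")
)

#' Generate synthetic event tables with ground truth
#'
#' Deterministic for a fixed configuration (including its seed). Every
#' patient receives at least one ASCVD diagnosis inside the study window;
#' each infection episode emits an antibiotic/antiviral prescription and
#' inflates any CRP test falling in the episode window (7 d before to 60 d
#' after the prescription) strictly above the acute cap; creatinine
#' trajectories are inverted from stratum-specific target eGFR values
#' through the CKD-EPI 2021 equation.
#'
#' @param config A [generator_config()].
#' @return List with elements `store` (an [ehr_store()]) and `truth`:
#'   `truth$patients` carries the true CKD stratum and stage and the true
#'   SI-at-first-eligible indicator under the generator's own bookkeeping
#'   (first 90-day group of non-inflated post-diagnosis CRPs, geometric
#'   mean >= 2 mg/L); `truth$crp_events` flags which generated CRP values
#'   were infection-inflated.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  cfg <- config
  set.seed(cfg$seed)
  n <- cfg$n_patients
  d0 <- as.integer(cfg$study_start)
  d1 <- as.integer(cfg$study_end)
  span <- d1 - d0

  id <- sprintf("p%06d", seq_len(n))
  sex <- ifelse(stats::runif(n) < cfg$p_male, "male", "female")
  age_entry <- pmin(100, pmax(19, stats::rnorm(n, cfg$age_mean, cfg$age_sd)))

  # cohort entry: first ASCVD diagnosis, uniform with >= 120 d of potential
  # follow-up before the study end
  ascvd_day <- d0 + runif_days(n, span - 120L)
  birth_day <- ascvd_day - as.integer(round(age_entry * 365.25))

  # mortality: exponential time from cohort entry
  mort_rate <- -log(1 - cfg$annual_mortality)
  death_yrs <- stats::rexp(n, rate = max(mort_rate, 1e-12))
  death_day <- ascvd_day + as.integer(round(pmin(death_yrs, 500) * 365.25))
  died <- cfg$annual_mortality > 0 & death_day <= d1
  death_day[!died] <- NA_integer_
  end_day <- ifelse(died, death_day, d1)
  fu_yrs <- (end_day - ascvd_day) / 365.25

  # true renal stratum, induced through target eGFR / UACR levels
  ckd <- stats::runif(n) < cfg$p_ckd
  stage <- rep("none", n)
  stage[ckd] <- sample(names(cfg$ckd_stage_probs), sum(ckd), replace = TRUE,
                       prob = cfg$ckd_stage_probs)
  egfr_target <- numeric(n)
  egfr_target[stage == "none"] <- stats::runif(sum(stage == "none"), 67, 110)
  egfr_target[stage == "stage1/2"] <- stats::runif(sum(stage == "stage1/2"), 63, 95)
  egfr_target[stage == "stage3"] <- stats::runif(sum(stage == "stage3"), 32, 58)
  egfr_target[stage == "stage4"] <- stats::runif(sum(stage == "stage4"), 16, 29)
  egfr_target[stage == "stage5"] <- stats::runif(sum(stage == "stage5"), 5, 14)
  uacr_median <- numeric(n)
  alb <- stage == "stage1/2"
  uacr_median[alb] <- stats::qlnorm(
    stats::runif(sum(alb), stats::plnorm(32, log(60), 0.6), 1), log(60), 0.6)
  uacr_median[stage %in% c("stage3", "stage4", "stage5")] <-
    stats::rlnorm(sum(stage %in% c("stage3", "stage4", "stage5")), log(47), 0.8)
  uacr_median[stage == "none"] <- pmin(25, stats::rlnorm(sum(stage == "none"), log(10), 0.6))
  no_renal_data <- !ckd & stats::runif(n) < cfg$p_no_renal_data

  # ----- diagnoses ---------------------------------------------------------
  dxs <- list()
  add_dx <- function(pid, day, code) {
    data.frame(patient_id = pid, date = day,
               icd9_code = rep(code, length.out = length(pid)),
               stringsAsFactors = FALSE)
  }
  subtype_p <- c(coronary = 0.545, cerebrovascular = 0.423, pad = 0.077, other = 0.099)
  sub_flags <- sapply(names(subtype_p), function(s) stats::runif(n) < subtype_p[[s]])
  none <- rowSums(sub_flags) == 0
  sub_flags[none, "coronary"] <- TRUE
  # the chronologically first ASCVD code lands exactly on the entry day
  first_sub <- apply(sub_flags, 1L, function(z) which(z)[1L])
  for (s in seq_along(subtype_p)) {
    nm <- names(subtype_p)[s]
    has <- which(sub_flags[, nm])
    day <- ifelse(first_sub[has] == s, ascvd_day[has],
                  ascvd_day[has] + runif_days(length(has), pmax(0L, end_day[has] - ascvd_day[has])))
    dxs[[nm]] <- add_dx(id[has], day,
                        sample(GEN_CODES[[nm]], length(has), replace = TRUE))
  }
  has_stage_dx <- stage %in% names(GEN_CODES$ckd_stage_dx) &
    stats::runif(n) < cfg$p_ckd_dx_code
  w <- which(has_stage_dx)
  dxs$ckd <- add_dx(id[w], ascvd_day[w] - runif_days(length(w), 730L),
                    GEN_CODES$ckd_stage_dx[stage[w]])
  w <- which(stats::runif(n) < cfg$p_chronic_infection)
  chronic_inf <- seq_len(n) %in% w
  dxs$chronic <- add_dx(id[w], ascvd_day[w] - runif_days(length(w), 3650L),
                        sample(GEN_CODES$chronic_infection, length(w), replace = TRUE))
  has_cancer <- stats::runif(n) < cfg$p_cancer
  w <- which(has_cancer)
  cancer_day <- rep(NA_integer_, n)
  cancer_day[w] <- ascvd_day[w] - 2000L + runif_days(length(w), 2000L + pmax(0L, end_day[w] - ascvd_day[w]))
  dxs$cancer <- add_dx(id[w], cancer_day[w],
                       sample(GEN_CODES$malignancy, length(w), replace = TRUE))
  w <- which(stats::runif(n) < cfg$p_nmsc)
  dxs$nmsc <- add_dx(id[w], ascvd_day[w] - 1000L +
                       runif_days(length(w), 1000L + pmax(0L, end_day[w] - ascvd_day[w])),
                     GEN_CODES$nmsc)
  for (cm in names(cfg$comorbidity_prev)) {
    w <- which(stats::runif(n) < cfg$comorbidity_prev[[cm]])
    dxs[[cm]] <- add_dx(id[w], ascvd_day[w] - runif_days(length(w), 3650L),
                        GEN_CODES$comorbidity[[cm]])
  }
  diagnoses <- do.call(rbind, dxs)

  # ----- prescriptions -----------------------------------------------------
  rxs <- list()
  # infection episodes: one antibiotic/antiviral prescription each
  n_inf <- stats::rpois(n, cfg$infection_rate_per_year * fu_yrs)
  pid <- rep(seq_len(n), n_inf)
  inf_day <- ascvd_day[pid] + runif_days(length(pid), pmax(0L, end_day[pid] - ascvd_day[pid]))
  rxs$infection <- data.frame(patient_id = id[pid], date = inf_day,
                              atc_code = sample(GEN_CODES$antibiotic, length(pid), replace = TRUE),
                              stringsAsFactors = FALSE)
  episode <- data.frame(pidx = pid, day = inf_day)
  # immunosuppressant users: recurring prescriptions
  imm_user <- stats::runif(n) < cfg$p_immunosuppressant_user
  n_imm <- ifelse(imm_user, 1L + stats::rpois(n, 1.5), 0L)
  pid <- rep(seq_len(n), n_imm)
  rxs$imm <- data.frame(patient_id = id[pid],
                        date = ascvd_day[pid] + runif_days(length(pid), pmax(0L, end_day[pid] - ascvd_day[pid])),
                        atc_code = sample(GEN_CODES$immunosuppressant, length(pid), replace = TRUE),
                        stringsAsFactors = FALSE)
  # background drug classes (never antibiotics/antivirals/immunosuppressants)
  for (cl in names(cfg$drug_class_prev)) {
    exposed <- stats::runif(n) < cfg$drug_class_prev[[cl]]
    n_rx <- ifelse(exposed, 1L + stats::rpois(n, 1.5 * pmax(fu_yrs, 0.25)), 0L)
    pid <- rep(seq_len(n), n_rx)
    lo <- ascvd_day[pid] - 365L
    rxs[[cl]] <- data.frame(patient_id = id[pid],
                            date = lo + runif_days(length(pid), end_day[pid] - lo),
                            atc_code = rep(GEN_CODES$drug_class[[cl]], length(pid)),
                            stringsAsFactors = FALSE)
  }
  prescriptions <- do.call(rbind, rxs)

  # ----- laboratory results ------------------------------------------------
  lab_list <- list()
  lab_span <- pmax(0L, end_day - (ascvd_day - 548L))
  lab_yrs <- lab_span / 365.25
  # serum creatinine from target eGFR (with log-scale measurement noise),
  # inverted through the CKD-EPI 2021 equation at the measurement date
  n_scr <- ifelse(no_renal_data, 0L, stats::rpois(n, cfg$creatinine_rate_per_year * lab_yrs))
  pid <- rep(seq_len(n), n_scr)
  scr_day <- (ascvd_day[pid] - 548L) + runif_days(length(pid), lab_span[pid])
  egfr_meas <- egfr_target[pid] * exp(stats::rnorm(length(pid), 0, cfg$egfr_noise_sd))
  age_meas <- (scr_day - birth_day[pid]) / 365.25
  lab_list$scr <- data.frame(patient_id = id[pid], date = scr_day,
                             analyte = rep("serum_creatinine", length(pid)),
                             value = round(creatinine_for_egfr(egfr_meas, age_meas, sex[pid]), 3),
                             stringsAsFactors = FALSE)
  n_uacr <- ifelse(no_renal_data, 0L, stats::rpois(n, cfg$uacr_rate_per_year * lab_yrs))
  pid <- rep(seq_len(n), n_uacr)
  uacr_val <- uacr_median[pid] * exp(stats::rnorm(length(pid), 0, 0.15))
  uacr_val[stage[pid] == "none"] <- pmin(29.5, uacr_val[stage[pid] == "none"])
  uacr_val[stage[pid] == "stage1/2"] <- pmax(30.5, uacr_val[stage[pid] == "stage1/2"])
  lab_list$uacr <- data.frame(patient_id = id[pid],
                              date = (ascvd_day[pid] - 548L) + runif_days(length(pid), lab_span[pid]),
                              analyte = rep("uacr", length(pid)),
                              value = round(uacr_val, 1),
                              stringsAsFactors = FALSE)
  # other routine labs: patient-level mean plus measurement noise
  lab_means <- list(haemoglobin = c(13.4, 1.9, 0.05),
                    total_cholesterol = c(174, 40, 0.07),
                    hdl_c = c(48, 12, 0.08), ldl_c = c(100, 33, 0.1),
                    triglycerides = c(125, 55, 0.15))
  for (an in names(lab_means)) {
    m <- lab_means[[an]]
    mu_i <- pmax(m[1] / 4, stats::rnorm(n, m[1], m[2]))
    n_l <- stats::rpois(n, cfg$lab_rate_per_year * lab_yrs)
    pid <- rep(seq_len(n), n_l)
    lab_list[[an]] <- data.frame(
      patient_id = id[pid],
      date = (ascvd_day[pid] - 548L) + runif_days(length(pid), lab_span[pid]),
      analyte = rep(an, length(pid)),
      value = round(mu_i[pid] * exp(stats::rnorm(length(pid), 0, m[3])), 1),
      stringsAsFactors = FALSE)
  }

  # CRP: baseline truncated log-normal per stratum with an optional
  # per-patient intercept; infection episodes inflate concurrent tests
  mu_log <- ifelse(ckd, log(cfg$crp_log_median[["ckd"]]),
                   log(cfg$crp_log_median[["non_ckd"]]))
  b_i <- stats::rnorm(n, 0, cfg$crp_patient_intercept_sd)
  sd_within <- sqrt(cfg$crp_log_sigma^2 - cfg$crp_patient_intercept_sd^2)
  n_crp <- stats::rpois(n, cfg$crp_rate_per_year * fu_yrs)
  pid <- rep(seq_len(n), n_crp)
  crp_day <- ascvd_day[pid] + runif_days(length(pid), pmax(0L, end_day[pid] - ascvd_day[pid]))
  pre_span <- pmax(0L, ascvd_day - d0)
  n_pre <- stats::rpois(n, cfg$pre_ascvd_crp_rate * pre_span / 365.25)
  n_pre[pre_span == 0L] <- 0L
  pid_pre <- rep(seq_len(n), n_pre)
  crp_day <- c(crp_day, d0 + runif_days(length(pid_pre), pre_span[pid_pre] - 1L))
  pid <- c(pid, pid_pre)
  crp_val <- rlnorm_trunc(length(pid), mu_log[pid] + b_i[pid], sd_within, cfg$crp_cap)
  # flag tests inside any infection episode window [rx - 7 d, rx + 60 d]
  inflated <- rep(FALSE, length(pid))
  if (nrow(episode) > 0L && length(pid) > 0L) {
    crp_dt <- data.table::data.table(pidx = pid, lo = crp_day - 60L,
                                     hi = crp_day + 7L, row = seq_along(pid))
    ep_dt <- data.table::data.table(pidx = episode$pidx, day = episode$day)
    hits <- ep_dt[crp_dt, on = .(pidx, day >= lo, day <= hi), nomatch = NULL, .(row = i.row)]
    inflated[unique(hits$row)] <- TRUE
  }
  crp_val[inflated] <- cfg$crp_cap +
    stats::rlnorm(sum(inflated), log(15), 0.8)
  lab_list$crp <- data.frame(patient_id = id[pid], date = crp_day,
                             analyte = rep("crp", length(pid)),
                             value = round(crp_val, 2),
                             stringsAsFactors = FALSE)
  labs <- do.call(rbind, lab_list)

  # ----- vitals ------------------------------------------------------------
  vital_means <- list(bmi = c(29.4, 5.0, 0.03), sbp = c(136, 18, 0.06),
                      dbp = c(78, 10, 0.07))
  vital_list <- list()
  for (vk in names(vital_means)) {
    m <- vital_means[[vk]]
    mu_i <- pmax(m[1] / 3, stats::rnorm(n, m[1], m[2]))
    n_v <- stats::rpois(n, cfg$vital_rate_per_year * lab_yrs)
    pid <- rep(seq_len(n), n_v)
    vital_list[[vk]] <- data.frame(
      patient_id = id[pid],
      date = (ascvd_day[pid] - 548L) + runif_days(length(pid), lab_span[pid]),
      kind = rep(vk, length(pid)),
      value = round(mu_i[pid] * exp(stats::rnorm(length(pid), 0, m[3])), 1),
      stringsAsFactors = FALSE)
  }
  vitals <- do.call(rbind, vital_list)

  # ----- patients ----------------------------------------------------------
  smoking <- sample(c("current", "former", "never", "unknown"), n,
                    replace = TRUE, prob = c(0.22, 0.25, 0.48, 0.05))
  retired <- stats::runif(n) < ifelse(age_entry >= 65, 0.90, 0.15)
  reimb <- sample(c(100, 90, 95, 40, 50, 60), n, replace = TRUE,
                  prob = c(0.08, 0.05, 0.05, 0.42, 0.25, 0.15))
  min_earn <- stats::runif(n) < cfg$p_minimum_earnings
  patients <- data.frame(
    patient_id = id, sex = sex,
    birth_date = as.Date(birth_day, origin = "1970-01-01"),
    death_date = as.Date(death_day, origin = "1970-01-01"),
    reimbursement_rate_pct = reimb, retired = retired,
    minimum_earnings = min_earn, smoking_status = smoking,
    smoking_date = as.Date(ascvd_day - runif_days(n, 1000L), origin = "1970-01-01"),
    stringsAsFactors = FALSE)

  to_date <- function(df) { df$date <- as.Date(df$date, origin = "1970-01-01"); df }
  store <- ehr_store(patients, to_date(diagnoses), to_date(prescriptions),
                     to_date(labs), to_date(vitals))

  # ----- ground truth ------------------------------------------------------
  crp_events <- data.frame(patient_id = lab_list$crp$patient_id,
                           date = as.Date(lab_list$crp$date, origin = "1970-01-01"),
                           value = lab_list$crp$value,
                           infection_inflated = inflated,
                           stringsAsFactors = FALSE)
  truth_pat <- data.frame(patient_id = id, ckd = ckd, ckd_stage = stage,
                          first_ascvd_date = as.Date(ascvd_day, origin = "1970-01-01"),
                          no_renal_data = no_renal_data,
                          chronic_infection = chronic_inf,
                          stringsAsFactors = FALSE)
  truth_pat$si_first_eligible <- truth_si_first(crp_events, truth_pat)

  list(store = store,
       truth = list(patients = truth_pat, crp_events = crp_events))
}

# generator-side bookkeeping of SI at the first eligible measurement:
# geometric mean of the non-inflated post-diagnosis CRPs within 90 days of
# the earliest one; NA when the patient has none
truth_si_first <- function(crp_events, truth_pat) {
  ev <- data.table::data.table(
    patient_id = crp_events$patient_id,
    day = as.integer(as.Date(crp_events$date)),
    value = crp_events$value,
    inflated = crp_events$infection_inflated)
  fa <- data.table::data.table(patient_id = truth_pat$patient_id,
                               fa_day = as.integer(truth_pat$first_ascvd_date))
  ev[fa, on = "patient_id", fa_day := i.fa_day]
  ev <- ev[!inflated & day >= fa_day]
  data.table::setorder(ev, patient_id, day)
  si <- ev[, {
    grp <- day <= day[1L] + 90L
    .(si = exp(mean(log(value[grp]))) >= 2)
  }, by = patient_id]
  out <- si$si[match(truth_pat$patient_id, si$patient_id)]
  out
}

#' Summarize generator ground truth
#'
#' True stratum prevalences and true SI proportions with their
#' denominators (the full generated cohort for strata; patients with at
#' least one usable CRP for SI).
#'
#' @param truth The `truth` element returned by [simulate_cohort()].
#' @return Data frame: `metric`, `stratum`, `numerator`, `denominator`,
#'   `proportion`.
#' @export
truth_summary <- function(truth) {
  tp <- truth$patients
  if (is.null(tp) || nrow(tp) == 0L) stop("empty ground truth")
  n <- nrow(tp)
  row <- function(metric, stratum, num, den) {
    data.frame(metric = metric, stratum = stratum, numerator = num,
               denominator = den, proportion = if (den > 0) num / den else NA_real_,
               stringsAsFactors = FALSE)
  }
  out <- list(row("ckd", "overall", sum(tp$ckd), n))
  for (st in setdiff(unique(tp$ckd_stage), "none")) {
    out <- c(out, list(row("ckd_stage", st, sum(tp$ckd_stage == st), sum(tp$ckd))))
  }
  evaluable <- !is.na(tp$si_first_eligible)
  out <- c(out, list(
    row("si_first_eligible", "overall", sum(tp$si_first_eligible[evaluable]), sum(evaluable)),
    row("si_first_eligible", "ckd", sum(tp$si_first_eligible[evaluable & tp$ckd]),
        sum(evaluable & tp$ckd)),
    row("si_first_eligible", "non_ckd", sum(tp$si_first_eligible[evaluable & !tp$ckd]),
        sum(evaluable & !tp$ckd))))
  do.call(rbind, out)
}
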