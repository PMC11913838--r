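# eGFR (CKD-EPI 2021), CKD classification and staging.
#
# CKD at a reference date is defined as any of:
#   * a stage >= 3 CKD diagnosis code on or before the reference date,
#   * most recent prior eGFR < 60 mL/min/1.73 m^2 (CKD-EPI 2021 from stored
#     serum creatinine; the formula is applied at classification time so it
#     remains the single source of truth),
#   * most recent prior UACR >= 30 mg/g.
# Patients with no creatinine measurement and no CKD diagnosis get status
# "unknown". Stage bands follow KDIGO convention on the same most recent
# eGFR: stage5 < 15, stage4 in [15, 30), stage3 in [30, 60); eGFR >= 60
# with UACR >= 30 is stage 1/2; a diagnosis-only CKD with no band match is
# stage "unknown".

CKD_STATUS <- c("CKD", "no-CKD", "unknown")
CKD_STAGES <- c("stage5", "stage4", "stage3", "stage1/2", "unknown")

#' Estimated glomerular filtration rate, CKD-EPI 2021 (creatinine, no race)
#'
#' eGFR = 142 * min(Scr/k, 1)^a * max(Scr/k, 1)^-1.200 * 0.9938^age *
#' 1.012 (if female), with k = 0.7 (F) / 0.9 (M) and a = -0.241 (F) /
#' -0.302 (M). Strictly decreasing in creatinine and in age.
#'
#' @param scr Serum creatinine, mg/dL (> 0). Vectorized.
#' @param age Age in years (>= 18).
#' @param sex `"male"` or `"female"`.
#' @return eGFR in mL/min/1.73 m^2.
#' @examples
#' egfr_ckd_epi_2021(1.0, 50, "male")    # ~91.7
#' egfr_ckd_epi_2021(0.7, 40, "female")  # ~112.1
#' @export
egfr_ckd_epi_2021 <- function(scr, age, sex) {
  if (any(is.na(scr)) || any(scr <= 0)) stop("serum creatinine must be positive")
  if (!all(sex %in% c("male", "female"))) stop("sex must be 'male' or 'female'")
  female <- sex == "female"
  kappa <- ifelse(female, 0.7, 0.9)
  alpha <- ifelse(female, -0.241, -0.302)
  r <- scr / kappa
  142 * pmin(r, 1)^alpha * pmax(r, 1)^(-1.200) * 0.9938^age *
    ifelse(female, 1.012, 1)
}

# invert the 2021 equation: creatinine giving a target eGFR for age/sex;
# used by the synthetic generator to induce CKD mechanistically
creatinine_for_egfr <- function(egfr, age, sex) {
  female <- sex == "female"
  kappa <- ifelse(female, 0.7, 0.9)
  alpha <- ifelse(female, -0.241, -0.302)
  a <- egfr / (142 * 0.9938^age * ifelse(female, 1.012, 1))
  ifelse(a < 1, kappa * a^(-1 / 1.2), kappa * a^(1 / alpha))
}

latest_before <- function(events, ref, strict = FALSE) {
  # events: patient_id, date, value; ref: patient_id, reference_date
  # returns per patient in ref the most recent event on/before (or strictly
  # before) the reference date
  ev <- data.table::data.table(patient_id = events$patient_id,
                               date = as.Date(events$date), value = events$value)
  data.table::setorder(ev, patient_id, date)
  rf <- data.table::data.table(patient_id = ref$patient_id,
                               ref_date = as.Date(ref$reference_date))
  lim <- if (strict) rf$ref_date - 1L else rf$ref_date
  rf[, .lim := lim]
  res <- ev[rf, on = .(patient_id, date <= .lim), mult = "last",
            .(patient_id = i.patient_id, reference_date = i.ref_date,
              value = x.value, date = x.date)]
  data.table::setDF(res)
  res
}

#' Classify CKD status and stage at a reference date
#'
#' Applies the three-criterion CKD definition per patient at its reference
#' date (typically the index date, or the data cutoff). Under the default
#' `egfr_rule = "latest"` the eGFR criterion uses the most recent prior
#' creatinine (current-status semantics); `"any"` instead fires if any
#' historical prior eGFR was below the threshold.
#'
#' @param store An [ehr_store()].
#' @param code_lists Code-list collection containing `ckd_stage3plus`.
#' @param reference Data frame `patient_id`, `reference_date`.
#' @param egfr_threshold eGFR criterion, mL/min/1.73 m^2 (default 60).
#' @param uacr_threshold UACR criterion, mg/g (default 30, inclusive).
#' @param egfr_rule `"latest"` (default) or `"any"`.
#' @param stage_bands eGFR band edges `c(stage5 = 15, stage4 = 30)`.
#' @return Data frame (one row per row of `reference`): `patient_id`,
#'   `reference_date`, `latest_egfr`, `egfr_date`, `latest_uacr`,
#'   `uacr_date`, `ckd_dx` (stage >= 3 diagnosis on/before reference),
#'   `ckd_status` in CKD / no-CKD / unknown, `ckd_stage` (NA unless CKD).
#' @export
classify_ckd <- function(store, code_lists, reference,
                         egfr_threshold = 60, uacr_threshold = 30,
                         egfr_rule = c("latest", "any"),
                         stage_bands = c(stage5 = 15, stage4 = 30)) {
  stopifnot(inherits(store, "ehr_store"))
  egfr_rule <- match.arg(egfr_rule)
  labs <- store$labs
  pats <- store$patients
  ref <- data.frame(patient_id = reference$patient_id,
                    reference_date = as.Date(reference$reference_date))

  scr <- labs[labs$analyte == "serum_creatinine", c("patient_id", "date", "value")]
  uacr <- labs[labs$analyte == "uacr", c("patient_id", "date", "value")]

  # eGFR computed from creatinine at its measurement date
  bd <- pats$birth_date[match(scr$patient_id, pats$patient_id)]
  sx <- pats$sex[match(scr$patient_id, pats$patient_id)]
  age_at_meas <- as.numeric(as.Date(scr$date) - bd) / 365.25
  egfr_tab <- data.frame(patient_id = scr$patient_id, date = scr$date,
                         value = egfr_ckd_epi_2021(scr$value, age_at_meas, sx))

  last_egfr <- latest_before(egfr_tab, ref)
  last_uacr <- latest_before(uacr, ref)

  dx <- store$diagnoses
  ckd_dx_tab <- dx[concept_match(dx$icd9_code, get_concept(code_lists, "ckd_stage3plus")), ]
  ckd_dx_tab$value <- rep(1, nrow(ckd_dx_tab))
  first_dx <- latest_before(ckd_dx_tab, ref)

  # "unknown" requires no eGFR-evaluable measurement and no CKD diagnosis at
  # all (existence, not window-restricted)
  has_any_scr <- ref$patient_id %in% scr$patient_id
  has_any_dx <- ref$patient_id %in% ckd_dx_tab$patient_id
  egfr_fires <- !is.na(last_egfr$value) & last_egfr$value < egfr_threshold
  if (egfr_rule == "any") {
    anylow <- data.frame(patient_id = egfr_tab$patient_id, date = egfr_tab$date,
                         value = as.numeric(egfr_tab$value < egfr_threshold))
    anylow <- latest_before(anylow[anylow$value == 1, ], ref)
    egfr_fires <- !is.na(anylow$value)
  }
  uacr_fires <- !is.na(last_uacr$value) & last_uacr$value >= uacr_threshold
  dx_fires <- !is.na(first_dx$value)

  status <- ifelse(dx_fires | egfr_fires | uacr_fires, "CKD",
                   ifelse(has_any_scr | has_any_dx, "no-CKD", "unknown"))

  stage <- rep(NA_character_, nrow(ref))
  g <- last_egfr$value
  u <- last_uacr$value
  is_ckd <- status == "CKD"
  stage[is_ckd] <- "unknown"
  stage[is_ckd & !is.na(g) & g < stage_bands[["stage5"]]] <- "stage5"
  stage[is_ckd & !is.na(g) & g >= stage_bands[["stage5"]] & g < stage_bands[["stage4"]]] <- "stage4"
  stage[is_ckd & !is.na(g) & g >= stage_bands[["stage4"]] & g < egfr_threshold] <- "stage3"
  stage[is_ckd & !is.na(g) & g >= egfr_threshold & !is.na(u) & u >= uacr_threshold] <- "stage1/2"

  data.frame(patient_id = ref$patient_id, reference_date = ref$reference_date,
             latest_egfr = last_egfr$value, egfr_date = last_egfr$date,
             latest_uacr = last_uacr$value, uacr_date = last_uacr$date,
             ckd_dx = dx_fires,
             ckd_status = factor(status, levels = CKD_STATUS),
             ckd_stage = factor(stage, levels = CKD_STAGES),
             stringsAsFactors = FALSE)
}

#' Assign CKD stage labels from a renal assessment
#'
#' Re-derives the stage band for rows already classified as CKD; calling it
#' on any non-CKD row is an error (stage is only defined within CKD).
#'
#' @param assessment Output of [classify_ckd()] restricted to CKD rows.
#' @param egfr_threshold,uacr_threshold,stage_bands As in [classify_ckd()].
#' @return Factor of stage labels.
#' @export
assign_stage <- function(assessment, egfr_threshold = 60, uacr_threshold = 30,
                         stage_bands = c(stage5 = 15, stage4 = 30)) {
  if (any(assessment$ckd_status != "CKD")) {
    stop("assign_stage() called on rows with ckd_status != 'CKD'")
  }
  g <- assessment$latest_egfr
  u <- assessment$latest_uacr
  stage <- rep("unknown", nrow(assessment))
  stage[!is.na(g) & g < stage_bands[["stage5"]]] <- "stage5"
  stage[!is.na(g) & g >= stage_bands[["stage5"]] & g < stage_bands[["stage4"]]] <- "stage4"
  stage[!is.na(g) & g >= stage_bands[["stage4"]] & g < egfr_threshold] <- "stage3"
  stage[!is.na(g) & g >= egfr_threshold & !is.na(u) & u >= uacr_threshold] <- "stage1/2"
  factor(stage, levels = CKD_STAGES)
}
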