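# Baseline characteristics and drug-utilization tables by SI status.
#
# Lookback conventions: laboratory and clinical measurements take the most
# recent value strictly before the index date within an 18-month (548 d)
# window; demographics and smoking use the most recent value on or before
# the index date, uncapped; comorbidity history is any diagnosis strictly
# before the index date (the cancer flag additionally requires the code
# more than 3 years before); drug exposure windows are [index - 365 d,
# index) pre and (index, index + 365 d] post, so the index day belongs to
# neither (no double counting).

BASELINE_LABS <- c("uacr", "haemoglobin", "total_cholesterol",
                   "hdl_c", "ldl_c", "triglycerides")

#' Standard comorbidity concepts flagged at baseline
#' @export
COMORBIDITY_CONCEPTS <- c("diabetes", "hypertension", "copd", "dementia",
                          "heart_failure", "atrial_fibrillation", "ibd",
                          "rheumatoid_disease", "cns_inflammatory_disease",
                          "liver_disease")

#' Standard pharmacological classes reported in utilization tables
#' @export
DRUG_CLASS_CONCEPTS <- c("corticosteroids", "immunosuppressants_rx",
                         "antibiotics", "antivirals", "antimycotics",
                         "antiplatelet_agents", "aspirin", "anticoagulants",
                         "nsaids", "acei_arb", "mra", "beta_blockers",
                         "diuretics", "calcium_channel_blockers",
                         "glucose_lowering", "sglt2_inhibitors",
                         "glp1_receptor_agonists", "statins",
                         "other_lipid_lowering", "ezetimibe",
                         "pcsk9_inhibitors", "omega3",
                         "fibrates_resins_nicotinic", "other_bp_medications",
                         "colchicine")

#' Extract per-patient baseline values
#'
#' For each laboratory analyte and clinical measurement, the most recent
#' value dated in `[index - lookback_days, index)` (strictly before the
#' index date); eGFR is computed from the baseline creatinine with the
#' CKD-EPI 2021 equation at its measurement date. Smoking status is the
#' most recent observation on or before the index date, with no lookback
#' cap.
#'
#' @param index_records Cohort index records.
#' @param store The [ehr_store()].
#' @param lookback_days Lab/vital lookback (default 548 d = 18 months).
#' @return Wide data frame, one row per patient: `egfr`, each analyte in
#'   `BASELINE_LABS`, `bmi`, `sbp`, `dbp`, `smoking_status`,
#'   `current_smoker`, plus `crp` (the grouped value at index).
#' @export
extract_baseline <- function(index_records, store, lookback_days = 548) {
  stopifnot(inherits(store, "ehr_store"))
  out <- data.frame(patient_id = index_records$patient_id,
                    stringsAsFactors = FALSE)
  idx <- data.frame(patient_id = index_records$patient_id,
                    reference_date = as.Date(index_records$index_date))

  window_latest <- function(events) {
    if (nrow(events) == 0L) return(rep(NA_real_, nrow(idx)))
    res <- latest_before(events, idx, strict = TRUE)
    inside <- !is.na(res$date) &
      res$date >= (idx$reference_date - lookback_days)
    ifelse(inside, res$value, NA_real_)
  }

  labs <- store$labs
  scr <- labs[labs$analyte == "serum_creatinine", c("patient_id", "date", "value")]
  if (nrow(scr) > 0L) {
    pats <- store$patients
    bd <- pats$birth_date[match(scr$patient_id, pats$patient_id)]
    sx <- pats$sex[match(scr$patient_id, pats$patient_id)]
    age <- as.numeric(as.Date(scr$date) - bd) / 365.25
    scr$value <- egfr_ckd_epi_2021(scr$value, age, sx)
  }
  out$egfr <- window_latest(scr)
  for (an in BASELINE_LABS) {
    out[[an]] <- window_latest(labs[labs$analyte == an,
                                    c("patient_id", "date", "value")])
  }
  vt <- store$vitals
  for (vk in VITAL_KINDS) {
    out[[vk]] <- window_latest(vt[vt$kind == vk, c("patient_id", "date", "value")])
  }
  pats <- store$patients
  m <- match(out$patient_id, pats$patient_id)
  sm <- pats$smoking_status[m]
  sm_date <- pats$smoking_date[m]
  sm[is.na(sm) | (!is.na(sm_date) & sm_date > idx$reference_date)] <- "unknown"
  out$smoking_status <- sm
  out$current_smoker <- sm == "current"
  out$crp <- index_records$crp_at_index
  out
}

#' Comorbidity history flags
#'
#' One logical flag per configured concept: any matching diagnosis strictly
#' before the index date. The cancer flag (malignancy excluding
#' non-melanoma skin cancer) additionally requires the code more than
#' `cancer_min_days` (default 1095 d = 3 years) before the index date.
#'
#' @param index_records Cohort index records.
#' @param diagnoses Diagnoses table.
#' @param code_lists Code-list collection.
#' @param concepts Concept names to flag (default the standard set).
#' @param cancer_min_days Minimum age of the cancer code, days.
#' @return Data frame: `patient_id`, one logical column per concept plus
#'   `cancer`.
#' @export
comorbidity_history <- function(index_records, diagnoses, code_lists,
                                concepts = COMORBIDITY_CONCEPTS,
                                cancer_min_days = 1095) {
  idx <- data.table::data.table(patient_id = index_records$patient_id,
                                index_date = as.Date(index_records$index_date))
  out <- data.frame(patient_id = index_records$patient_id,
                    stringsAsFactors = FALSE)
  flag_before <- function(sub, max_date_offset = -1L) {
    if (nrow(sub) == 0L) return(rep(FALSE, nrow(idx)))
    dt <- data.table::data.table(patient_id = sub$patient_id,
                                 date = as.Date(sub$date))
    lim <- data.table::copy(idx)[, .lim := index_date + max_date_offset]
    hit <- dt[lim, on = .(patient_id, date <= .lim), mult = "first", x.date]
    !is.na(hit)
  }
  for (cn in concepts) {
    sub <- diagnoses[concept_match(diagnoses$icd9_code, get_concept(code_lists, cn)), ]
    out[[cn]] <- flag_before(sub)
  }
  mal <- diagnoses[concept_match(diagnoses$icd9_code, get_concept(code_lists, "malignancy")) &
                     !concept_match(diagnoses$icd9_code,
                                    get_concept(code_lists, "non_melanoma_skin_cancer")), ]
  out$cancer <- flag_before(mal, max_date_offset = -(cancer_min_days + 1L))
  out
}

#' Drug-exposure flags in a window around the index date
#'
#' Exposure = at least one matching prescription in
#' `[index - window_days, index)` for `window = "pre"` or
#' `(index, index + window_days]` for `window = "post"`.
#'
#' @param index_records Cohort index records.
#' @param prescriptions Prescriptions table.
#' @param code_lists Code-list collection.
#' @param classes Drug-class concept names (default the standard set).
#' @param window `"pre"` or `"post"`.
#' @param window_days Window length, days (default 365 = 12 months).
#' @return Data frame: `patient_id`, one logical column per class.
#' @export
drug_utilization <- function(index_records, prescriptions, code_lists,
                             classes = DRUG_CLASS_CONCEPTS,
                             window = c("pre", "post"), window_days = 365) {
  window <- match.arg(window)
  idx <- data.table::data.table(patient_id = index_records$patient_id,
                                index_date = as.Date(index_records$index_date))
  if (window == "pre") {
    idx[, `:=`(.lo = index_date - window_days, .hi = index_date - 1L)]
  } else {
    idx[, `:=`(.lo = index_date + 1L, .hi = index_date + window_days)]
  }
  out <- data.frame(patient_id = index_records$patient_id,
                    stringsAsFactors = FALSE)
  for (cl in classes) {
    sub <- prescriptions[concept_match(prescriptions$atc_code,
                                       get_concept(code_lists, cl)), ]
    if (nrow(sub) == 0L) { out[[cl]] <- rep(FALSE, nrow(idx)); next }
    dt <- data.table::data.table(patient_id = sub$patient_id,
                                 date = as.Date(sub$date))
    hit <- dt[idx, on = .(patient_id, date >= .lo, date <= .hi),
              mult = "first", x.date]
    out[[cl]] <- !is.na(hit)
  }
  out
}

#' Two-group comparison p-value
#'
#' Test choice by declared variable kind (the defaults of this package, as
#' the source analyses name no tests): categorical -> chi-squared;
#' approximately normal continuous -> Welch two-sample t-test; skewed
#' continuous -> Wilcoxon rank-sum. Degenerate inputs (a constant variable,
#' an empty group or cell) yield NA rather than an error. No
#' multiple-testing correction is applied.
#'
#' @param x Variable values (numeric, logical or factor).
#' @param group Two-level grouping vector.
#' @param kind `"continuous"`, `"skewed"` or `"categorical"`.
#' @return A p-value in \[0, 1\], or NA.
#' @export
compare_groups <- function(x, group, kind = c("continuous", "skewed", "categorical")) {
  kind <- match.arg(kind)
  keep <- !is.na(x) & !is.na(group)
  x <- x[keep]; group <- group[keep]
  if (length(unique(group)) != 2L) return(NA_real_)
  p <- tryCatch(switch(kind,
    continuous = {
      if (any(tapply(x, group, function(v) length(v) < 2 || stats::var(v) == 0))) {
        NA_real_
      } else stats::t.test(x ~ group)$p.value
    },
    skewed = {
      if (length(unique(x)) < 2L) NA_real_
      else stats::wilcox.test(x ~ group, exact = FALSE)$p.value
    },
    categorical = {
      tab <- table(x, group)
      if (nrow(tab) < 2L || ncol(tab) < 2L) NA_real_
      else suppressWarnings(stats::chisq.test(tab, correct = FALSE)$p.value)
    }), error = function(e) NA_real_)
  p
}

fmt_mean_sd <- function(x) sprintf("%.2f ± %.2f", mean(x, na.rm = TRUE),
                                   stats::sd(x, na.rm = TRUE))
fmt_median_iqr <- function(x) {
  q <- stats::quantile(x, c(0.25, 0.5, 0.75), na.rm = TRUE)
  sprintf("%.1f [%.1f, %.1f]", q[2], q[1], q[3])
}
fmt_pct <- function(x) sprintf("%.1f%%", 100 * mean(x, na.rm = TRUE))

#' Build a baseline-characteristics table by SI status
#'
#' One row per variable, with overall / SI / non-SI summaries (mean +/- SD,
#' median \[IQR\] for skewed variables, or %), a missingness count, and the
#' two-group comparison p-value from [compare_groups()].
#'
#' @param index_records Cohort index records.
#' @param baseline Output of [extract_baseline()].
#' @param comorbidities Output of [comorbidity_history()].
#' @return Data frame of class `baseline_table`.
#' @export
baseline_table <- function(index_records, baseline, comorbidities) {
  si <- index_records$si_at_index
  grp <- ifelse(si, "SI", "no-SI")
  rows <- list()
  add <- function(variable, x, kind) {
    fmt <- switch(kind, continuous = fmt_mean_sd, skewed = fmt_median_iqr,
                  categorical = fmt_pct)
    rows[[length(rows) + 1L]] <<- data.frame(
      variable = variable, kind = kind,
      overall = fmt(x), si = fmt(x[si]), non_si = fmt(x[!si]),
      n_missing = sum(is.na(x)),
      p_value = compare_groups(x, grp, kind),
      stringsAsFactors = FALSE)
  }
  add("age_years", index_records$age_at_index, "continuous")
  add("female_sex", index_records$sex == "female", "categorical")
  add("current_smoker", baseline$current_smoker, "categorical")
  add("low_ses", index_records$low_ses, "categorical")
  add("bmi", baseline$bmi, "continuous")
  add("sbp", baseline$sbp, "continuous")
  add("dbp", baseline$dbp, "continuous")
  add("crp", baseline$crp, "skewed")
  add("egfr", baseline$egfr, "continuous")
  add("uacr", baseline$uacr, "skewed")
  add("haemoglobin", baseline$haemoglobin, "continuous")
  add("total_cholesterol", baseline$total_cholesterol, "continuous")
  add("hdl_c", baseline$hdl_c, "continuous")
  add("ldl_c", baseline$ldl_c, "continuous")
  add("triglycerides", baseline$triglycerides, "continuous")
  for (s in c("coronary", "cerebrovascular", "pad", "other")) {
    add(paste0("ascvd_", s), index_records[[s]], "categorical")
  }
  add("ckd", index_records$ckd_status == "CKD", "categorical")
  for (st in setdiff(CKD_STAGES, NA)) {
    in_ckd <- index_records$ckd_status == "CKD"
    x <- ifelse(in_ckd, index_records$ckd_stage == st, NA)
    add(paste0("ckd_", gsub("/", "", st)), x, "categorical")
  }
  for (cm in setdiff(names(comorbidities), "patient_id")) {
    add(cm, comorbidities[[cm]], "categorical")
  }
  out <- do.call(rbind, rows)
  attr(out, "n") <- c(overall = length(si), si = sum(si), non_si = sum(!si))
  class(out) <- c("baseline_table", "data.frame")
  out
}

#' Build a drug-utilization table by SI status
#'
#' Percentage of patients exposed to each pharmacological class in the
#' chosen window, per group, with chi-squared p-values.
#'
#' @param index_records Cohort index records.
#' @param utilization Output of [drug_utilization()].
#' @param window Label carried into the output (`"pre"`/`"post"`).
#' @return Data frame: class, window, overall/SI/non-SI percentages,
#'   p-value.
#' @export
utilization_table <- function(index_records, utilization, window = "pre") {
  si <- index_records$si_at_index
  grp <- ifelse(si, "SI", "no-SI")
  classes <- setdiff(names(utilization), "patient_id")
  do.call(rbind, lapply(classes, function(cl) {
    x <- utilization[[cl]]
    data.frame(drug_class = cl, window = window,
               overall_pct = 100 * mean(x), si_pct = 100 * mean(x[si]),
               non_si_pct = 100 * mean(x[!si]),
               p_value = compare_groups(x, grp, "categorical"),
               stringsAsFactors = FALSE)
  }))
}
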