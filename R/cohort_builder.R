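# Cohort assembly: ASCVD identification, patient-level exclusions,
# index records and the attrition flowchart.

#' First ASCVD diagnosis date and subtype flags per patient
#'
#' A patient's first ASCVD date is the minimum date over all diagnoses
#' matching the four ASCVD subtype concepts (coronary, cerebrovascular,
#' peripheral arterial disease, other atherosclerotic disease). Subtype
#' flags record every subtype ever coded, so they are non-exclusive and
#' their cohort percentages may sum above 100.
#'
#' @param diagnoses Diagnoses table (`patient_id`, `date`, `icd9_code`).
#' @param code_lists Collection with concepts `ascvd_coronary`,
#'   `ascvd_cerebrovascular`, `ascvd_pad`, `ascvd_other`.
#' @return Data frame: `patient_id`, `first_ascvd_date`, logical columns
#'   `coronary`, `cerebrovascular`, `pad`, `other`. Patients with no ASCVD
#'   code are absent.
#' @export
first_ascvd <- function(diagnoses, code_lists) {
  subtype_concepts <- c(coronary = "ascvd_coronary",
                        cerebrovascular = "ascvd_cerebrovascular",
                        pad = "ascvd_pad", other = "ascvd_other")
  hits <- lapply(subtype_concepts, function(cn) {
    concept_match(diagnoses$icd9_code, get_concept(code_lists, cn))
  })
  any_hit <- Reduce(`|`, hits)
  if (!any(any_hit)) {
    out <- data.frame(patient_id = character(0),
                      first_ascvd_date = as.Date(character(0)))
    for (s in names(subtype_concepts)) out[[s]] <- logical(0)
    return(out)
  }
  dt <- data.table::data.table(patient_id = diagnoses$patient_id[any_hit],
                               date = as.Date(diagnoses$date)[any_hit])
  for (s in names(subtype_concepts)) dt[, (s) := hits[[s]][any_hit]]
  out <- dt[, c(.(first_ascvd_date = min(date)),
                lapply(.SD, any)),
            by = patient_id, .SDcols = names(subtype_concepts)]
  data.table::setorder(out, patient_id)
  data.table::setDF(out)
  out
}

#' Derive the low socioeconomic status flag
#'
#' Low SES: minimum earnings, or a drug reimbursement rate of 100%, or
#' non-retired with a reimbursement rate >= 90%. Absent fields never
#' qualify; the number of patients with any absent SES field is attached as
#' attribute `n_missing_ses`.
#'
#' @param patients Patients table.
#' @return Logical vector aligned with `patients` rows.
#' @export
derive_low_ses <- function(patients) {
  reimb <- patients$reimbursement_rate_pct
  retired <- patients$retired
  min_earn <- patients$minimum_earnings
  missing_any <- is.na(reimb) | is.na(retired) | is.na(min_earn)
  f <- function(x) !is.na(x) & x
  low <- f(min_earn) |
    (!is.na(reimb) & reimb == 100) |
    (f(!retired) & !is.na(reimb) & reimb >= 90)
  structure(low, n_missing_ses = sum(missing_any))
}

#' Apply patient-level exclusions
#'
#' Retains patients aged >= 18 years at the index date with no
#' chronic-infection diagnosis at any time ("ever" semantics: chronic
#' conditions do not resolve).
#'
#' @param candidates Data frame with `age_at_index` and logical
#'   `chronic_infection`.
#' @return The retained rows.
#' @export
apply_patient_exclusions <- function(candidates) {
  keep <- candidates$age_at_index >= 18 & !candidates$chronic_infection
  candidates[keep, , drop = FALSE]
}

#' Assemble the analysis cohort and its attrition flowchart
#'
#' End-to-end cohort construction: identify ASCVD patients and their
#' subtype flags, flag chronic infections, run the CRP eligibility engine,
#' assign index dates, apply the age and chronic-infection exclusions, and
#' classify CKD status/stage at the index date.
#'
#' @param store An [ehr_store()].
#' @param code_lists Code-list collection (see [default_code_lists()]).
#' @param si_threshold SI threshold, mg/L (default 2, inclusive).
#' @param group_window_days CRP grouping window, days (default 90).
#' @param egfr_rule Passed to [classify_ckd()].
#' @param ... Window overrides passed to the eligibility engine.
#' @return List of class `ascvd_cohort`:
#'   `index_records` (one row per included patient: identifiers, first
#'   ASCVD and index dates, SI status and CRP at index, CKD status/stage,
#'   subtype flags, age at index, sex, low SES, death date),
#'   `eligible` (all grouped eligible CRP records of included patients),
#'   `exclusions` (per raw CRP rule labels), and `flowchart`.
#' @export
build_cohort <- function(store, code_lists, si_threshold = 2,
                         group_window_days = 90,
                         egfr_rule = c("latest", "any"), ...) {
  stopifnot(inherits(store, "ehr_store"))
  egfr_rule <- match.arg(egfr_rule)
  pats <- store$patients
  dx <- store$diagnoses

  fa <- first_ascvd(dx, code_lists)
  chronic <- unique(dx$patient_id[
    concept_match(dx$icd9_code, get_concept(code_lists, "chronic_infection"))])

  elig <- crp_eligibility(store, code_lists, fa,
                          group_window_days = group_window_days, ...)
  idx <- assign_index(elig$eligible, threshold = si_threshold)

  ir <- merge(fa, idx, by = "patient_id")
  ir <- merge(ir, pats[, c("patient_id", "sex", "birth_date", "death_date",
                           "reimbursement_rate_pct", "retired", "minimum_earnings")],
              by = "patient_id")
  ir$age_at_index <- as.numeric(ir$index_date - ir$birth_date) / 365.25
  ir$chronic_infection <- ir$patient_id %in% chronic
  ir$low_ses <- as.logical(derive_low_ses(ir))

  # age at index is only evaluable for patients with an index date; the
  # flowchart's exclusion stage therefore removes chronic infections plus
  # the evaluable minors
  minors <- ir$patient_id[ir$age_at_index < 18]
  excluded_pids <- union(chronic, minors)

  ir <- apply_patient_exclusions(ir)

  renal <- classify_ckd(store, code_lists,
                        data.frame(patient_id = ir$patient_id,
                                   reference_date = ir$index_date),
                        egfr_rule = egfr_rule)
  ir$ckd_status <- renal$ckd_status
  ir$ckd_stage <- renal$ckd_stage
  ir$latest_egfr <- renal$latest_egfr
  ir$latest_uacr <- renal$latest_uacr

  keep <- c("patient_id", "first_ascvd_date", "index_date", "si_at_index",
            "crp_at_index", "ckd_status", "ckd_stage", "latest_egfr",
            "latest_uacr", "coronary", "cerebrovascular", "pad", "other",
            "age_at_index", "sex", "low_ses", "death_date")
  index_records <- ir[, keep]
  rownames(index_records) <- NULL

  eligible <- elig$eligible[elig$eligible$patient_id %in% index_records$patient_id, ]

  crps <- store$labs[store$labs$analyte == "crp", ]
  retained_pids <- setdiff(fa$patient_id, excluded_pids)
  fl <- build_flowchart(
    n_identified = nrow(fa),
    n_after_exclusions = length(retained_pids),
    n_with_crp = length(intersect(retained_pids, unique(crps$patient_id))),
    n_included = nrow(index_records))

  structure(list(index_records = index_records, eligible = eligible,
                 exclusions = elig$exclusions, flowchart = fl),
            class = "ascvd_cohort")
}

#' Attrition flowchart counts
#'
#' Four-stage accounting: patients identified with ASCVD; remaining after
#' the age / chronic-infection exclusions; of those, with at least one CRP
#' measurement; of those, with at least one eligible grouped CRP
#' (= included). Counts must be non-increasing, otherwise the internal
#' accounting is inconsistent and the function aborts.
#'
#' @param n_identified,n_after_exclusions,n_with_crp,n_included Stage counts.
#' @return Data frame `stage`, `n` of class `flowchart`.
#' @export
build_flowchart <- function(n_identified, n_after_exclusions, n_with_crp,
                            n_included) {
  counts <- c(identified_ascvd = n_identified,
              after_patient_exclusions = n_after_exclusions,
              with_crp_measurement = n_with_crp,
              with_eligible_crp = n_included)
  if (any(diff(counts) > 0)) {
    stop("flowchart counts are not non-increasing: ",
         paste(counts, collapse = " -> "))
  }
  structure(data.frame(stage = names(counts), n = as.integer(counts),
                       row.names = NULL), class = c("flowchart", "data.frame"))
}

#' @export
print.ascvd_cohort <- function(x, ...) {
  cat("<ascvd_cohort>\n")
  print(x$flowchart)
  ir <- x$index_records
  cat(sprintf("  SI at index: %d / %d (%.1f%%)\n", sum(ir$si_at_index),
              nrow(ir), 100 * mean(ir$si_at_index)))
  invisible(x)
}
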