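# The three prevalence estimands, stratified variants, and the
# inflammatory-disease sensitivity analysis.
#
# Estimands:
#   at_first_crp    SI at the first eligible (grouped) CRP, over all
#                   included patients;
#   point_at_cutoff SI among patients alive at the data cutoff with >= 1
#                   eligible grouped CRP anchored in the prior 18 months
#                   (548 d), status from the most recent such record;
#   period          any SI-qualifying eligible grouped CRP during the
#                   study, over all included patients.
# Binomial CIs are Wilson intervals (well-behaved near 0 and 1); the
# underlying study reported none, so these are an artifact of this
# implementation. Zero-denominator strata are reported as missing (NA),
# never as zero.

#' Wilson score confidence interval for a binomial proportion
#'
#' @param x Successes. @param n Trials. @param conf Confidence level.
#' @return Matrix with columns `lower`, `upper` (NA rows where n = 0).
#' @export
wilson_ci <- function(x, n, conf = 0.95) {
  z <- stats::qnorm(1 - (1 - conf) / 2)
  p <- ifelse(n > 0, x / n, NA_real_)
  denom <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  cbind(lower = pmax(0, centre - half), upper = pmin(1, centre + half))
}

#' Construct prevalence estimates
#'
#' Validates counts (0 <= numerator <= denominator), computes the
#' proportion and its Wilson interval, and attaches the estimand and
#' stratum labels. Vectorized.
#'
#' @param numerator,denominator Counts.
#' @param estimand One of `"at_first_crp"`, `"point_at_cutoff"`, `"period"`.
#' @param stratifier,stratum Label columns (default overall).
#' @return Data frame: estimand, stratifier, stratum, numerator,
#'   denominator, proportion, ci_lower, ci_upper.
#' @export
prevalence_estimate <- function(numerator, denominator,
                                estimand = c("at_first_crp", "point_at_cutoff", "period"),
                                stratifier = "overall", stratum = "overall") {
  estimand <- match.arg(estimand)
  if (length(numerator) == 0L) {
    return(data.frame(estimand = character(0), stratifier = character(0),
                      stratum = character(0), numerator = integer(0),
                      denominator = integer(0), proportion = numeric(0),
                      ci_lower = numeric(0), ci_upper = numeric(0)))
  }
  if (any(numerator < 0) || any(denominator < 0) || any(numerator > denominator)) {
    stop("invalid counts: need 0 <= numerator <= denominator")
  }
  ci <- wilson_ci(numerator, denominator)
  data.frame(estimand = estimand, stratifier = stratifier, stratum = stratum,
             numerator = as.integer(numerator), denominator = as.integer(denominator),
             proportion = ifelse(denominator > 0, numerator / denominator, NA_real_),
             ci_lower = ci[, "lower"], ci_upper = ci[, "upper"],
             stringsAsFactors = FALSE)
}

#' Age bands used in stratified analyses
#'
#' @param age Age in years.
#' @return Factor with levels `<65`, `65-74`, `>=75`.
#' @export
age_band <- function(age) {
  cut(age, breaks = c(-Inf, 65, 75, Inf), right = FALSE,
      labels = c("<65", "65-74", ">=75"))
}

stratum_of <- function(index_records, by) {
  switch(by,
    overall = rep("overall", nrow(index_records)),
    ckd_status = as.character(index_records$ckd_status),
    ckd_stage = as.character(index_records$ckd_stage),
    sex = index_records$sex,
    age_band = as.character(age_band(index_records$age_at_index)),
    stop("unknown stratifier '", by, "'")
  )
}

prevalence_by <- function(index_records, flag, estimand, by) {
  strat <- stratum_of(index_records, by)
  keep <- !is.na(strat)
  tab_n <- table(strat[keep])
  tab_x <- tapply(flag[keep], strat[keep], sum)
  out <- prevalence_estimate(as.integer(tab_x[names(tab_n)]), as.integer(tab_n),
                             estimand = estimand, stratifier = by,
                             stratum = names(tab_n))
  rownames(out) <- NULL
  out
}

#' Prevalence of systemic inflammation at the first eligible CRP
#'
#' Numerator: patients whose first eligible grouped CRP was >= 2 mg/L
#' (`si_at_index`); denominator: all included patients (or the stratum
#' subset). Empty strata are absent from the output rather than reported
#' as zero.
#'
#' @param index_records Cohort index records (see [build_cohort()]).
#' @param by Stratifier: `"overall"`, `"ckd_status"`, `"ckd_stage"`,
#'   `"sex"`, or `"age_band"`; may be a vector of several.
#' @return Prevalence-estimate data frame.
#' @export
prevalence_at_first_crp <- function(index_records, by = "overall") {
  do.call(rbind, lapply(by, function(b) {
    prevalence_by(index_records, index_records$si_at_index, "at_first_crp", b)
  }))
}

#' Point prevalence of systemic inflammation at the data cutoff
#'
#' Denominator: patients alive at the cutoff (death date absent or after
#' it) with at least one eligible grouped CRP anchored within
#' `lookback_days` before the cutoff (inclusive). Numerator under the
#' default `status_rule = "latest"`: those whose most recent such record is
#' >= `threshold`; `"any"` instead counts any qualifying record in the
#' window.
#'
#' @param index_records Cohort index records.
#' @param eligible Grouped eligible CRP records ([group_geometric()]).
#' @param cutoff_date Data cutoff date; must lie inside the study window.
#' @param study_start,study_end Study window used to validate the cutoff.
#' @param lookback_days Lookback length in days (18 months = 548 d).
#' @param threshold SI threshold, mg/L.
#' @param status_rule `"latest"` (default) or `"any"`.
#' @param by Stratifier(s), as in [prevalence_at_first_crp()].
#' @return Prevalence-estimate data frame.
#' @export
point_prevalence_at_cutoff <- function(index_records, eligible, cutoff_date,
                                       study_start = "2014-01-01",
                                       study_end = "2023-07-31",
                                       lookback_days = 548, threshold = 2,
                                       status_rule = c("latest", "any"),
                                       by = "overall") {
  status_rule <- match.arg(status_rule)
  cutoff <- as.Date(cutoff_date)
  if (cutoff < as.Date(study_start) || cutoff > as.Date(study_end)) {
    stop("cutoff date ", format(cutoff), " lies outside the study window")
  }
  el <- eligible[as.Date(eligible$anchor_date) >= cutoff - lookback_days &
                   as.Date(eligible$anchor_date) <= cutoff, ]
  dt <- data.table::data.table(patient_id = el$patient_id,
                               anchor_date = as.Date(el$anchor_date),
                               value = el$value)
  data.table::setorder(dt, patient_id, anchor_date)
  status <- if (status_rule == "latest") {
    dt[, .(si = value[.N] >= threshold), by = patient_id]
  } else {
    dt[, .(si = any(value >= threshold)), by = patient_id]
  }
  alive <- is.na(index_records$death_date) | index_records$death_date > cutoff
  in_denom <- alive & index_records$patient_id %in% status$patient_id
  ir <- index_records[in_denom, , drop = FALSE]
  flag <- status$si[match(ir$patient_id, status$patient_id)]
  do.call(rbind, lapply(by, function(b) {
    prevalence_by(ir, flag, "point_at_cutoff", b)
  }))
}

#' Period prevalence of systemic inflammation
#'
#' Numerator: patients with any eligible grouped CRP >= `threshold` during
#' the study period; denominator: all included patients. Always at least
#' the at-first-CRP numerator (set containment).
#'
#' @inheritParams point_prevalence_at_cutoff
#' @return Prevalence-estimate data frame.
#' @export
period_prevalence <- function(index_records, eligible, threshold = 2,
                              by = "overall") {
  dt <- data.table::data.table(patient_id = eligible$patient_id,
                               value = eligible$value)
  ever <- dt[, .(si = any(value >= threshold)), by = patient_id]
  flag <- index_records$patient_id %in% ever$patient_id[ever$si]
  do.call(rbind, lapply(by, function(b) {
    prevalence_by(index_records, flag, "period", b)
  }))
}

#' Sensitivity analysis: exclude inflammatory and rheumatoid disease
#'
#' Recomputes all three estimands on the subcohort of patients without any
#' inflammatory/rheumatoid diagnosis strictly before their index date.
#'
#' @param index_records Cohort index records.
#' @param eligible Grouped eligible CRP records.
#' @param diagnoses Diagnoses table.
#' @param code_lists Collection with concept `inflammatory_rheumatoid`.
#' @param cutoff_date,study_start,study_end,lookback_days,threshold,by As
#'   in the primary estimators.
#' @return Prevalence-estimate data frame over the three estimands, with a
#'   column `analysis = "sensitivity_no_inflammatory"`.
#' @export
sensitivity_exclude_inflammatory <- function(index_records, eligible, diagnoses,
                                             code_lists, cutoff_date,
                                             study_start = "2014-01-01",
                                             study_end = "2023-07-31",
                                             lookback_days = 548, threshold = 2,
                                             by = "overall") {
  infl <- diagnoses[concept_match(diagnoses$icd9_code,
                                  get_concept(code_lists, "inflammatory_rheumatoid")), ]
  dt <- data.table::data.table(patient_id = infl$patient_id,
                               date = as.Date(infl$date))
  ir <- data.table::data.table(patient_id = index_records$patient_id,
                               index_date = as.Date(index_records$index_date))
  ir[, lim := index_date - 1L]
  hit <- dt[ir, on = .(patient_id, date <= lim), mult = "first", nomatch = NA, x.date]
  keep <- is.na(hit)
  sub <- index_records[keep, , drop = FALSE]
  sub_el <- eligible[eligible$patient_id %in% sub$patient_id, , drop = FALSE]
  out <- rbind(
    prevalence_at_first_crp(sub, by = by),
    point_prevalence_at_cutoff(sub, sub_el, cutoff_date,
                               study_start = study_start, study_end = study_end,
                               lookback_days = lookback_days,
                               threshold = threshold, by = by),
    period_prevalence(sub, sub_el, threshold = threshold, by = by))
  out$analysis <- "sensitivity_no_inflammatory"
  out
}
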