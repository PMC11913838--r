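# CRP eligibility rules, geometric-mean grouping, index-date assignment.
#
# A raw CRP measurement is ineligible if it was recorded
#   (i)   before the patient's first ASCVD diagnosis,
#   (ii)  concomitantly with an active infection: value > 20 mg/L, or taken
#         within 2 months after or 7 days before an antibiotic/antiviral
#         prescription,
#   (iii) less than 3 months after an immunosuppressant prescription,
#   (iv)  less than 3 years after a malignancy diagnosis (non-melanoma skin
#         cancer excepted).
# Calendar-unit windows are fixed-day approximations: 2 months = 60 d,
# 3 months = 90 d, 3 years = 1095 d (all configurable). "Within" intervals
# are inclusive at both ends; "less than" intervals are exclusive at the far
# end; ">20 mg/L" is strict; the inflammation threshold ">=2 mg/L" is
# inclusive. Eligible measurements within 3 months (90 d) of each other are
# grouped greedily from the earliest and averaged with a geometric mean;
# the group carries its anchor (earliest member) date.

EXCLUSION_RULES <- c("pre-ASCVD", "value>20", "infection-window",
                     "immunosuppressant-window", "cancer-window", "none")

as_day <- function(x) as.integer(as.Date(x))

# ---------------------------------------------------------------------------
# Reference single-patient filters. These are the readable, loop-style
# statements of the rules (any() over all CRP x event pairs); the cohort
# engine below must agree with them record for record.

#' Drop CRP measurements taken before the first ASCVD diagnosis
#'
#' Rule (i): a measurement is retained iff its date is on or after the
#' first ASCVD diagnosis date ("before" is strict, so the diagnosis day
#' itself is retained).
#'
#' @param crps Data frame with columns `date` (Date) and `value` (mg/L).
#' @param first_ascvd_date The patient's first ASCVD diagnosis date.
#' @return The retained rows of `crps`.
#' @export
filter_pre_ascvd <- function(crps, first_ascvd_date) {
  stopifnot(length(first_ascvd_date) == 1L)
  crps[as.Date(crps$date) >= as.Date(first_ascvd_date), , drop = FALSE]
}

#' Drop CRP measurements reflecting active infection
#'
#' Rule (ii): excluded iff value > 20 mg/L (strict), or some
#' antibiotic/antiviral prescription date p satisfies
#' p in \[t - after_days, t + before_days\] for CRP date t
#' (default: within 2 months = 60 d after, or 7 d before, a prescription;
#' both ends inclusive).
#'
#' @param crps Data frame with `date`, `value`.
#' @param rx_dates Dates of antibiotic/antiviral prescriptions.
#' @param cap Acute-phase value cap in mg/L (default 20).
#' @param after_days,before_days Window half-widths in days.
#' @return The retained rows of `crps`.
#' @export
filter_infection <- function(crps, rx_dates, cap = 20,
                             after_days = 60, before_days = 7) {
  t <- as_day(crps$date); p <- as_day(rx_dates)
  in_window <- vapply(t, function(ti) any(p >= ti - after_days & p <= ti + before_days),
                      logical(1))
  if (length(p) == 0L) in_window <- rep(FALSE, length(t))
  crps[!(crps$value > cap | in_window), , drop = FALSE]
}

#' Drop CRP measurements under recent immunosuppressant exposure
#'
#' Rule (iii): excluded iff taken less than `window_days` (default
#' 3 months = 90 d) after an immunosuppressant prescription, i.e. some
#' prescription date p satisfies 0 <= t - p < 90. The rule is one-sided:
#' measurements before the prescription are unaffected.
#'
#' @inheritParams filter_infection
#' @param rx_dates Immunosuppressant prescription dates.
#' @param window_days Washout length in days.
#' @return The retained rows of `crps`.
#' @export
filter_immunosuppressant <- function(crps, rx_dates, window_days = 90) {
  t <- as_day(crps$date); p <- as_day(rx_dates)
  hit <- vapply(t, function(ti) any(ti - p >= 0 & ti - p < window_days), logical(1))
  if (length(p) == 0L) hit <- rep(FALSE, length(t))
  crps[!hit, , drop = FALSE]
}

#' Drop CRP measurements taken during active cancer
#'
#' Rule (iv): excluded iff taken less than `window_days` (default
#' 3 years = 1095 d) after a malignancy diagnosis. The supplied diagnosis
#' dates must already exclude non-melanoma skin cancer codes.
#'
#' @inheritParams filter_infection
#' @param dx_dates Malignancy diagnosis dates (non-melanoma skin cancer
#'   removed).
#' @param window_days Active-cancer window in days.
#' @return The retained rows of `crps`.
#' @export
filter_cancer <- function(crps, dx_dates, window_days = 1095) {
  t <- as_day(crps$date); d <- as_day(dx_dates)
  hit <- vapply(t, function(ti) any(ti - d >= 0 & ti - d < window_days), logical(1))
  if (length(d) == 0L) hit <- rep(FALSE, length(t))
  crps[!hit, , drop = FALSE]
}

# ---------------------------------------------------------------------------
# Cohort-scale engine (data.table non-equi joins)

# TRUE where an event for the same patient falls in [date + lo, date + hi]
has_event_within <- function(crp_dt, events, lo, hi) {
  if (nrow(crp_dt) == 0L || is.null(events) || nrow(events) == 0L) {
    return(rep(FALSE, nrow(crp_dt)))
  }
  cr <- data.table::data.table(patient_id = crp_dt$patient_id,
                               .lo = crp_dt$day + lo, .hi = crp_dt$day + hi,
                               .row = seq_len(nrow(crp_dt)))
  ev <- data.table::data.table(patient_id = events$patient_id,
                               day = as_day(events$date))
  hit_rows <- ev[cr, on = .(patient_id, day >= .lo, day <= .hi),
                 nomatch = NULL, .(row = i..row)]
  out <- rep(FALSE, nrow(crp_dt))
  out[unique(hit_rows$row)] <- TRUE
  out
}

#' Label every raw CRP measurement with the first eligibility rule it fires
#'
#' Applies the four exclusion rules to all CRP measurements of a cohort and
#' assigns exactly one label per record: the first firing rule in the order
#' pre-ASCVD, value>20, infection-window, immunosuppressant-window,
#' cancer-window, or "none" (eligible). Retention is the conjunction of all
#' rules, so the order affects labels only, never the retained set.
#' Measurements of patients with no ASCVD diagnosis are labelled pre-ASCVD.
#'
#' @param crps Data frame of raw CRP measurements: `patient_id`, `date`,
#'   `value` (mg/L).
#' @param first_ascvd Data frame `patient_id`, `first_ascvd_date`.
#' @param abx_rx Antibiotic/antiviral prescriptions (`patient_id`, `date`).
#' @param imm_rx Immunosuppressant prescriptions (`patient_id`, `date`).
#' @param cancer_dx Malignancy diagnoses excluding non-melanoma skin cancer
#'   (`patient_id`, `date`).
#' @param crp_cap Acute-phase cap, mg/L (default 20, strict).
#' @param infection_after_days,infection_before_days Rule (ii) window
#'   (default 60 d after / 7 d before a prescription, inclusive).
#' @param immunosuppressant_days Rule (iii) washout (default 90 d,
#'   exclusive far end).
#' @param cancer_days Rule (iv) window (default 1095 d, exclusive far end).
#' @return `crps` with an added factor column `rule` (levels in rule order
#'   plus `"none"`).
#' @export
label_crp_exclusions <- function(crps, first_ascvd, abx_rx = NULL, imm_rx = NULL,
                                 cancer_dx = NULL, crp_cap = 20,
                                 infection_after_days = 60, infection_before_days = 7,
                                 immunosuppressant_days = 90, cancer_days = 1095) {
  crps <- as.data.frame(crps)
  dt <- data.table::data.table(patient_id = crps$patient_id,
                               day = as_day(crps$date), value = crps$value)
  fa <- data.table::data.table(patient_id = first_ascvd$patient_id,
                               fa_day = as_day(first_ascvd$first_ascvd_date))
  dt[fa, on = "patient_id", fa_day := i.fa_day]
  pre_ascvd <- is.na(dt$fa_day) | dt$day < dt$fa_day
  over_cap <- dt$value > crp_cap
  infection <- has_event_within(dt, abx_rx, -infection_after_days, infection_before_days)
  immuno <- has_event_within(dt, imm_rx, -(immunosuppressant_days - 1L), 0L)
  cancer <- has_event_within(dt, cancer_dx, -(cancer_days - 1L), 0L)
  rule <- rep("none", nrow(dt))
  rule[cancer] <- "cancer-window"
  rule[immuno] <- "immunosuppressant-window"
  rule[infection] <- "infection-window"
  rule[over_cap] <- "value>20"
  rule[pre_ascvd] <- "pre-ASCVD"
  crps$rule <- factor(rule, levels = EXCLUSION_RULES)
  crps
}

#' Group eligible CRP measurements within a rolling window by geometric mean
#'
#' Greedy anchoring from the earliest measurement: the first ungrouped
#' measurement anchors a group containing every measurement dated within
#' `window_days` (default 90 d = 3 months) of the anchor; the group's value
#' is the geometric mean of its members and its date is the anchor date.
#' Consecutive anchors are therefore more than `window_days` apart. The
#' result is invariant to the input row order (sorting is internal).
#'
#' @param crps Data frame of eligible measurements: `patient_id`, `date`,
#'   `value` with all values in (0, cap\].
#' @param window_days Grouping window in days.
#' @return Data frame of grouped records: `patient_id`, `anchor_date`,
#'   `value` (geometric mean, mg/L), `n_members`, plus list columns
#'   `member_dates`, `member_values`.
#' @examples
#' crp <- data.frame(patient_id = "p1",
#'                   date = as.Date("2020-01-01") + c(0, 30),
#'                   value = c(2, 8))
#' group_geometric(crp)$value  # sqrt(2 * 8) = 4
#' @export
group_geometric <- function(crps, window_days = 90) {
  crps <- as.data.frame(crps)
  if (any(crps$value <= 0)) {
    stop("geometric mean undefined: non-positive CRP value in input")
  }
  empty <- data.frame(patient_id = character(0), anchor_date = as.Date(character(0)),
                      value = numeric(0), n_members = integer(0))
  if (nrow(crps) == 0L) {
    empty$member_dates <- list(); empty$member_values <- list()
    return(empty)
  }
  dt <- data.table::data.table(patient_id = crps$patient_id,
                               date = as.Date(crps$date), value = crps$value)
  data.table::setorder(dt, patient_id, date, value)
  dt[, day := as.integer(date)]
  dt[, grp := 0L]
  g <- 0L
  # each pass assigns, per patient, the next anchor and all its members;
  # pass count = max number of groups for any one patient
  while (dt[, any(grp == 0L)]) {
    g <- g + 1L
    anchors <- dt[grp == 0L, .(.a = day[1L]), by = patient_id]
    dt[anchors, on = "patient_id", a := i..a]
    dt[grp == 0L & day <= a + window_days, grp := g]
    dt[, a := NULL]
  }
  # clamp against floating-point drift so min(members) <= gm <= max(members)
  # holds exactly
  out <- dt[, .(anchor_date = date[1L],
                value = pmin(pmax(exp(mean(log(value))), min(value)), max(value)),
                n_members = .N,
                member_dates = list(date),
                member_values = list(value)),
            by = .(patient_id, grp)]
  data.table::setorder(out, patient_id, anchor_date)
  out[, grp := NULL]
  data.table::setDF(out)
  out
}

#' Assign each patient's index date and inflammation status
#'
#' The index date is the anchor date of the patient's first eligible
#' grouped CRP record; systemic inflammation (SI) at index is defined as a
#' grouped value >= `threshold` mg/L (inclusive). Patients with no eligible
#' record are simply absent from the result (excluded from the cohort, not
#' an error).
#'
#' @param eligible Grouped records from [group_geometric()].
#' @param threshold SI threshold in mg/L (default 2).
#' @return Data frame: `patient_id`, `index_date`, `crp_at_index`,
#'   `si_at_index`.
#' @export
assign_index <- function(eligible, threshold = 2) {
  if (nrow(eligible) == 0L) {
    return(data.frame(patient_id = character(0), index_date = as.Date(character(0)),
                      crp_at_index = numeric(0), si_at_index = logical(0)))
  }
  dt <- data.table::as.data.table(eligible[, c("patient_id", "anchor_date", "value")])
  data.table::setorder(dt, patient_id, anchor_date)
  out <- dt[, .(index_date = anchor_date[1L], crp_at_index = value[1L]), by = patient_id]
  out[, si_at_index := crp_at_index >= threshold]
  data.table::setDF(out)
  out
}

#' Run the full CRP eligibility pipeline on an event store
#'
#' Extracts raw CRP measurements and the trigger events (antibiotic/
#' antiviral and immunosuppressant prescriptions, malignancy diagnoses with
#' non-melanoma skin cancer removed) from the store via the configured code
#' lists, labels every measurement with its exclusion rule, and groups the
#' retained measurements by geometric mean.
#'
#' @param store An [ehr_store()].
#' @param code_lists Named list of [code_list()] objects; must contain
#'   `antibiotic_antiviral`, `immunosuppressant`, `malignancy`,
#'   `non_melanoma_skin_cancer`.
#' @param first_ascvd Data frame `patient_id`, `first_ascvd_date` (from
#'   [first_ascvd()]).
#' @param group_window_days Grouping window, days (default 90).
#' @param ... Window overrides passed to [label_crp_exclusions()].
#' @return List: `eligible` (grouped records), `exclusions` (per raw CRP:
#'   `patient_id`, `date`, `value`, `rule`).
#' @export
crp_eligibility <- function(store, code_lists, first_ascvd,
                            group_window_days = 90, ...) {
  stopifnot(inherits(store, "ehr_store"))
  labs <- store$labs
  crps <- labs[labs$analyte == "crp", c("patient_id", "date", "value")]
  rx <- store$prescriptions
  dx <- store$diagnoses
  abx <- rx[concept_match(rx$atc_code, get_concept(code_lists, "antibiotic_antiviral")), ]
  imm <- rx[concept_match(rx$atc_code, get_concept(code_lists, "immunosuppressant")), ]
  mal <- dx[concept_match(dx$icd9_code, get_concept(code_lists, "malignancy")) &
              !concept_match(dx$icd9_code, get_concept(code_lists, "non_melanoma_skin_cancer")), ]
  labelled <- label_crp_exclusions(crps, first_ascvd,
                                   abx_rx = abx, imm_rx = imm, cancer_dx = mal, ...)
  retained <- labelled[labelled$rule == "none", c("patient_id", "date", "value")]
  list(eligible = group_geometric(retained, window_days = group_window_days),
       exclusions = labelled)
}
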