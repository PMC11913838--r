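# Shared fixtures and independent oracles for the test suite.

d <- function(x) as.Date(x)

empty_patients <- function() {
  data.frame(patient_id = character(0), sex = character(0),
              birth_date = character(0), stringsAsFactors = FALSE)
}

# minimal single/multi-patient store builder; missing tables default empty
make_store <- function(patients = NULL, diagnoses = NULL, prescriptions = NULL,
                       labs = NULL, vitals = NULL) {
  if (is.null(patients)) {
    patients <- data.frame(patient_id = "p1", sex = "male",
                           birth_date = "1950-06-15", stringsAsFactors = FALSE)
  }
  blank <- function(cols) {
    df <- as.data.frame(setNames(rep(list(character(0)), length(cols)), cols),
                        stringsAsFactors = FALSE)
    df
  }
  if (is.null(diagnoses)) diagnoses <- blank(c("patient_id", "date", "icd9_code"))
  if (is.null(prescriptions)) prescriptions <- blank(c("patient_id", "date", "atc_code"))
  if (is.null(labs)) labs <- blank(c("patient_id", "date", "analyte", "value"))
  if (is.null(vitals)) vitals <- blank(c("patient_id", "date", "kind", "value"))
  ehr_store(patients, diagnoses, prescriptions, labs, vitals)
}

crp_lab <- function(patient_id, date, value) {
  data.frame(patient_id = patient_id, date = as.character(date),
             analyte = "crp", value = value, stringsAsFactors = FALSE)
}

# ---------------------------------------------------------------------------
# Independent brute-force oracle for the eligibility rules: plain loops over
# every (CRP, event) pair, written directly from the rule statements.
oracle_label <- function(crps, first_ascvd, abx, imm, cancer,
                         cap = 20, inf_after = 60, inf_before = 7,
                         imm_days = 90, cancer_days = 1095) {
  n <- nrow(crps)
  out <- character(n)
  for (i in seq_len(n)) {
    pid <- crps$patient_id[i]
    t <- as.integer(as.Date(crps$date[i]))
    v <- crps$value[i]
    fa <- first_ascvd$first_ascvd_date[first_ascvd$patient_id == pid]
    rule <- "none"
    ca <- as.integer(as.Date(cancer$date[cancer$patient_id == pid]))
    if (length(ca) && any(t - ca >= 0 & t - ca < cancer_days)) rule <- "cancer-window"
    im <- as.integer(as.Date(imm$date[imm$patient_id == pid]))
    if (length(im) && any(t - im >= 0 & t - im < imm_days)) rule <- "immunosuppressant-window"
    ab <- as.integer(as.Date(abx$date[abx$patient_id == pid]))
    if (length(ab) && any(ab >= t - inf_after & ab <= t + inf_before)) rule <- "infection-window"
    if (v > cap) rule <- "value>20"
    if (length(fa) == 0 || t < as.integer(as.Date(fa))) rule <- "pre-ASCVD"
    out[i] <- rule
  }
  out
}

# independent greedy grouping oracle (single patient, scalar loop)
oracle_group <- function(dates, values, window = 90) {
  o <- order(dates)
  dates <- as.integer(as.Date(dates))[o]; values <- values[o]
  groups <- list()
  used <- rep(FALSE, length(dates))
  while (any(!used)) {
    a <- which(!used)[1]
    members <- !used & dates <= dates[a] + window
    groups[[length(groups) + 1]] <- list(
      anchor = dates[a], gm = exp(mean(log(values[members]))),
      n = sum(members))
    used <- used | members
  }
  groups
}

# independently coded CKD-EPI 2021 (scalar, explicit branches)
oracle_egfr <- function(scr, age, sex) {
  if (sex == "female") {
    k <- 0.7; a <- -0.241; s <- 1.012
  } else {
    k <- 0.9; a <- -0.302; s <- 1.0
  }
  ratio <- scr / k
  term <- if (ratio < 1) ratio^a else ratio^(-1.2)
  142 * term * 0.9938^age * s
}
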