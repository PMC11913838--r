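# Domain model: event tables, code lists, delimited-text readers/writers.
#
# The package works on five longitudinal event tables keyed by an opaque
# patient identifier, mirroring the structure of primary-care EHR extracts:
# patients, diagnoses (ICD-9), prescriptions (ATC), laboratory results and
# clinical measurements. All dates are ISO-8601 calendar dates; window
# arithmetic downstream is in whole days.

#' Closed set of laboratory analytes
#'
#' Analyte labels accepted in the `labs` table, with their units:
#' CRP (mg/L), serum creatinine (mg/dL), urinary albumin-to-creatinine
#' ratio (mg/g), haemoglobin (g/dL), total cholesterol, HDL-C, LDL-C and
#' triglycerides (all mg/dL).
#'
#' @export
LAB_ANALYTES <- c(
  "crp", "serum_creatinine", "uacr", "haemoglobin",
  "total_cholesterol", "hdl_c", "ldl_c", "triglycerides"
)

#' Closed set of clinical measurement kinds
#'
#' BMI (kg/m^2), systolic and diastolic blood pressure (mmHg).
#'
#' @export
VITAL_KINDS <- c("bmi", "sbp", "dbp")

SMOKING_LEVELS <- c("current", "former", "never", "unknown")

# ---------------------------------------------------------------------------
# Code lists

#' Create a code list for a named clinical concept
#'
#' A code list maps a concept (e.g. "statins", "coronary ASCVD") to a set
#' of ICD-9 or ATC code prefixes. Both vocabularies are hierarchical, so
#' membership is tested by string prefix: a code belongs to the concept iff
#' it starts with any configured prefix. Matching is case-sensitive and
#' dot-sensitive ("410." does not match "4101").
#'
#' @param concept_name Name of the concept.
#' @param system Coding system, `"ICD9"` or `"ATC"`.
#' @param prefixes Non-empty character vector of code prefixes.
#' @return An object of class `code_list`.
#' @examples
#' cl <- code_list("antibiotics", "ATC", "J01")
#' concept_match("J01CA04", cl)
#' @export
code_list <- function(concept_name, system = c("ICD9", "ATC"), prefixes) {
  system <- match.arg(system)
  prefixes <- as.character(prefixes)
  if (length(prefixes) == 0L || any(is.na(prefixes)) || any(!nzchar(prefixes))) {
    stop("code_list '", concept_name, "': prefixes must be non-empty strings")
  }
  structure(
    list(concept_name = concept_name, system = system,
         prefixes = unique(prefixes)),
    class = "code_list"
  )
}

#' @export
print.code_list <- function(x, ...) {
  cat(sprintf("<code_list> %s [%s]: %s\n", x$concept_name, x$system,
              paste(x$prefixes, collapse = ", ")))
  invisible(x)
}

#' Test codes against a concept's prefixes
#'
#' @param code Character vector of ICD-9 or ATC codes.
#' @param concept A `code_list`.
#' @return Logical vector: `TRUE` where the code starts with any prefix.
#' @export
concept_match <- function(code, concept) {
  stopifnot(inherits(concept, "code_list"))
  code <- as.character(code)
  hit <- rep(FALSE, length(code))
  for (p in concept$prefixes) hit <- hit | startsWith(code, p)
  hit
}

#' Look up a concept in a code-list collection
#'
#' @param code_lists Named list of `code_list` objects.
#' @param name Concept name.
#' @return The `code_list`; errors naming the available concepts if absent.
#' @export
get_concept <- function(code_lists, name) {
  if (!name %in% names(code_lists)) {
    stop("unknown concept '", name, "'; available concepts: ",
         paste(sort(names(code_lists)), collapse = ", "))
  }
  code_lists[[name]]
}

#' Read a code-list configuration file
#'
#' The file is YAML with a top-level `concepts:` mapping; each entry has a
#' `system` (ICD9 or ATC) and a list of `prefixes`. The code lists shipped
#' in `inst/extdata/default_codelists.yaml` are illustrative defaults (the
#' vocabulary layer is user-configurable), not an authoritative mapping.
#'
#' @param path Path to a YAML file.
#' @return Named list of `code_list` objects.
#' @export
read_code_lists <- function(path) {
  if (!file.exists(path)) stop("code-list file not found: ", path)
  raw <- yaml::read_yaml(path)
  if (is.null(raw$concepts)) stop("code-list file has no 'concepts' section")
  out <- lapply(names(raw$concepts), function(nm) {
    e <- raw$concepts[[nm]]
    code_list(nm, e$system, unlist(e$prefixes))
  })
  names(out) <- names(raw$concepts)
  out
}

#' Default illustrative code lists
#'
#' Convenience loader for the code lists shipped with the package.
#' @return Named list of `code_list` objects.
#' @export
default_code_lists <- function() {
  read_code_lists(system.file("extdata", "default_codelists.yaml",
                              package = "inflaprev", mustWork = TRUE))
}

# ---------------------------------------------------------------------------
# Event-table validation

parse_iso_date <- function(x) {
  # strict ISO-8601; anything else becomes NA and the row is rejected
  d <- as.Date(as.character(x), format = "%Y-%m-%d", optional = TRUE)
  d[is.na(x) | !grepl("^\\d{4}-\\d{2}-\\d{2}$", as.character(x))] <- as.Date(NA)
  d
}

require_columns <- function(df, cols, table) {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    stop("table '", table, "' is missing mandatory column(s): ",
         paste(missing, collapse = ", "))
  }
}

# Validate one event table; returns list(records, rejected) where rejected
# carries a human-readable reason per dropped row.
validate_table <- function(df, table) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  reasons <- rep(NA_character_, nrow(df))
  mark <- function(bad, why) {
    ifelse(bad & is.na(reasons), why, reasons)
  }
  switch(table,
    patients = {
      require_columns(df, c("patient_id", "sex", "birth_date"), table)
      for (col in c("death_date", "reimbursement_rate_pct", "retired",
                    "minimum_earnings", "smoking_status", "smoking_date")) {
        if (!col %in% names(df)) df[[col]] <- NA
      }
      df$birth_date <- parse_iso_date(df$birth_date)
      death_raw <- df$death_date
      df$death_date <- parse_iso_date(df$death_date)
      df$smoking_date <- parse_iso_date(df$smoking_date)
      df$reimbursement_rate_pct <- suppressWarnings(as.numeric(df$reimbursement_rate_pct))
      df$retired <- as.logical(df$retired)
      df$minimum_earnings <- as.logical(df$minimum_earnings)
      reasons <- mark(is.na(df$patient_id) | !nzchar(df$patient_id), "missing patient_id")
      reasons <- mark(!df$sex %in% c("male", "female"), "sex not in {male, female}")
      reasons <- mark(is.na(df$birth_date), "malformed birth_date")
      reasons <- mark(!is.na(death_raw) & nzchar(as.character(death_raw)) &
                        is.na(df$death_date), "malformed death_date")
      reasons <- mark(!is.na(df$death_date) & df$death_date < df$birth_date,
                      "death_date before birth_date")
      reasons <- mark(!is.na(df$reimbursement_rate_pct) &
                        (df$reimbursement_rate_pct < 0 | df$reimbursement_rate_pct > 100),
                      "reimbursement_rate_pct outside [0, 100]")
      reasons <- mark(!is.na(df$smoking_status) & !df$smoking_status %in% SMOKING_LEVELS,
                      "unknown smoking_status")
    },
    diagnoses = {
      require_columns(df, c("patient_id", "date", "icd9_code"), table)
      df$date <- parse_iso_date(df$date)
      reasons <- mark(is.na(df$patient_id) | !nzchar(df$patient_id), "missing patient_id")
      reasons <- mark(is.na(df$date), "malformed date")
      reasons <- mark(is.na(df$icd9_code) | !nzchar(df$icd9_code), "empty icd9_code")
    },
    prescriptions = {
      require_columns(df, c("patient_id", "date", "atc_code"), table)
      df$date <- parse_iso_date(df$date)
      reasons <- mark(is.na(df$patient_id) | !nzchar(df$patient_id), "missing patient_id")
      reasons <- mark(is.na(df$date), "malformed date")
      reasons <- mark(is.na(df$atc_code) | !nzchar(df$atc_code), "empty atc_code")
    },
    labs = {
      require_columns(df, c("patient_id", "date", "analyte", "value"), table)
      df$date <- parse_iso_date(df$date)
      df$value <- suppressWarnings(as.numeric(df$value))
      reasons <- mark(is.na(df$patient_id) | !nzchar(df$patient_id), "missing patient_id")
      reasons <- mark(is.na(df$date), "malformed date")
      reasons <- mark(!df$analyte %in% LAB_ANALYTES, "unknown analyte")
      reasons <- mark(is.na(df$value), "non-numeric value")
      reasons <- mark(!is.na(df$value) & df$value < 0, "negative value")
      # CRP of exactly 0 mg/L is rejected at parse time: downstream grouping
      # uses geometric means, undefined at 0 (assay floor).
      reasons <- mark(!is.na(df$value) & df$value == 0 & df$analyte == "crp",
                      "crp value of 0 (below assay floor)")
    },
    vitals = {
      require_columns(df, c("patient_id", "date", "kind", "value"), table)
      df$date <- parse_iso_date(df$date)
      df$value <- suppressWarnings(as.numeric(df$value))
      reasons <- mark(is.na(df$patient_id) | !nzchar(df$patient_id), "missing patient_id")
      reasons <- mark(is.na(df$date), "malformed date")
      reasons <- mark(!df$kind %in% VITAL_KINDS, "unknown measurement kind")
      reasons <- mark(is.na(df$value) | df$value <= 0, "non-positive value")
    },
    stop("unknown table: ", table)
  )
  bad <- !is.na(reasons)
  list(
    records = df[!bad, , drop = FALSE],
    rejected = data.frame(table = rep(table, sum(bad)),
                          row = which(bad),
                          reason = reasons[bad],
                          stringsAsFactors = FALSE)
  )
}

# ---------------------------------------------------------------------------
# The event store

#' Assemble a validated EHR event store
#'
#' Validates the five event tables against the type invariants (parseable
#' ISO dates, known analytes, non-negative lab values, ...). Rows violating
#' an invariant are rejected and counted; the rejection log is available via
#' [rejected_rows()].
#'
#' @param patients,diagnoses,prescriptions,labs,vitals Data frames with the
#'   documented column contracts.
#' @return An object of class `ehr_store`: a list of the five validated
#'   tables with a `rejected` attribute.
#' @export
ehr_store <- function(patients, diagnoses, prescriptions, labs, vitals) {
  tabs <- list(patients = patients, diagnoses = diagnoses,
               prescriptions = prescriptions, labs = labs, vitals = vitals)
  validated <- mapply(validate_table, tabs, names(tabs), SIMPLIFY = FALSE)
  store <- lapply(validated, `[[`, "records")
  rejected <- do.call(rbind, lapply(validated, `[[`, "rejected"))
  rownames(rejected) <- NULL
  if (anyDuplicated(store$patients$patient_id)) {
    stop("duplicate patient_id in patients table")
  }
  structure(store, rejected = rejected, class = "ehr_store")
}

#' Rejected-row log of an event store
#'
#' @param store An `ehr_store`.
#' @return Data frame with one row per rejected input row (table, row
#'   number, reason).
#' @export
rejected_rows <- function(store) {
  stopifnot(inherits(store, "ehr_store"))
  attr(store, "rejected")
}

#' @export
print.ehr_store <- function(x, ...) {
  cat("<ehr_store>\n")
  for (nm in names(x)) {
    cat(sprintf("  %-14s %8d records\n", nm, nrow(x[[nm]])))
  }
  nr <- nrow(attr(x, "rejected"))
  if (nr > 0) cat(sprintf("  (%d input rows rejected; see rejected_rows())\n", nr))
  invisible(x)
}

EHR_TABLES <- c("patients", "diagnoses", "prescriptions", "labs", "vitals")

#' Read the five event tables from delimited files
#'
#' One UTF-8 comma-delimited file per table with fixed documented headers.
#' Malformed rows (bad dates, unknown analytes, negative values) are
#' rejected with a counted reason; a missing mandatory column aborts.
#'
#' @param dir Directory containing `patients.csv`, `diagnoses.csv`,
#'   `prescriptions.csv`, `labs.csv`, `vitals.csv`; alternatively pass
#'   `paths`, a named list/vector of file paths.
#' @param paths Optional named character vector overriding `dir`.
#' @return A validated `ehr_store`.
#' @export
read_event_tables <- function(dir = NULL, paths = NULL) {
  if (is.null(paths)) {
    stopifnot(!is.null(dir))
    paths <- file.path(dir, paste0(EHR_TABLES, ".csv"))
    names(paths) <- EHR_TABLES
  }
  missing <- EHR_TABLES[!EHR_TABLES %in% names(paths)]
  if (length(missing)) stop("no path given for table(s): ", paste(missing, collapse = ", "))
  absent <- paths[!file.exists(unlist(paths[EHR_TABLES]))]
  if (length(absent)) stop("input table file(s) not found: ", paste(absent, collapse = ", "))
  tabs <- lapply(EHR_TABLES, function(tb) {
    data.table::fread(paths[[tb]], colClasses = "character",
                      na.strings = c("", "NA"), data.table = FALSE)
  })
  names(tabs) <- EHR_TABLES
  do.call(ehr_store, tabs)
}

#' Write an event store to delimited files
#'
#' Inverse of [read_event_tables()]: the write-then-read round trip
#' preserves the record multisets exactly.
#'
#' @param store An `ehr_store`.
#' @param dir Output directory (created if absent).
#' @return Invisibly, the named vector of file paths written.
#' @export
write_event_tables <- function(store, dir) {
  stopifnot(inherits(store, "ehr_store"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(EHR_TABLES, function(tb) {
    p <- file.path(dir, paste0(tb, ".csv"))
    df <- store[[tb]]
    for (col in names(df)) if (inherits(df[[col]], "Date")) {
      df[[col]] <- format(df[[col]], "%Y-%m-%d")
    }
    data.table::fwrite(df, p, na = "NA")
    p
  }, character(1))
  invisible(paths)
}
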