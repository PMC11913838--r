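Package: inflaprev
Title: Systemic Inflammation Phenotyping and Prevalence Estimation from
    Primary-Care EHR Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computable phenotyping of systemic inflammation (C-reactive
    protein >= 2 mg/L) in patients with atherosclerotic cardiovascular
    disease from longitudinal primary-care event tables. Implements the
    temporal-window eligibility rules for CRP measurements (post-diagnosis
    restriction, infection and immunosuppressant washout windows, active
    cancer exclusion), geometric-mean grouping of repeat measurements,
    CKD-EPI 2021 eGFR and KDIGO-style chronic kidney disease staging,
    cohort assembly with attrition accounting, three prevalence estimands
    (at first eligible measurement, point prevalence at a cutoff date,
    period prevalence) with stratified variants and a sensitivity analysis,
    baseline-characteristics and drug-utilization tables, and a seeded
    synthetic-cohort generator with exported ground truth for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table (>= 1.14),
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
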