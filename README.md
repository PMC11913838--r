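# inflaprev

Systemic inflammation phenotyping and prevalence estimation from
primary-care EHR data.

## The problem

Residual inflammatory risk is a recognised driver of recurrent events in
atherosclerotic cardiovascular disease (ASCVD), and it is usually
operationalised as a C-reactive protein (CRP) level ≥ 2 mg/L — the
threshold used by the CANTOS/JUPITER/RESCUE/ZEUS trial family. Estimating
how common this *systemic inflammation* (SI) phenotype is in a real-world
ASCVD population from routine electronic health records is not a simple
query: CRP is an acute-phase reactant, so raw measurements must first be
cleaned of acute infections, immunosuppressant effects and active cancer
before they can be read as a chronic inflammatory state.

`inflaprev` implements that computable phenotype and the downstream
epidemiology for researchers working with longitudinal primary-care event
tables (patients, ICD-9 diagnoses, ATC prescriptions, laboratory results,
clinical measurements):

* **CRP eligibility rules.** A measurement at time *t* is ineligible if
  (i) *t* precedes the first ASCVD diagnosis; (ii) it reflects active
  infection — value > 20 mg/L, or an antibiotic/antiviral prescription
  date *p* with *p* ∈ [*t* − 60 d, *t* + 7 d]; (iii) an immunosuppressant
  prescription satisfies 0 ≤ *t* − *p* < 90 d; (iv) a malignancy
  diagnosis (non-melanoma skin cancer excepted) satisfies
  0 ≤ *t* − *d* < 1095 d. Eligible measurements within 90 d are grouped
  greedily from the earliest and averaged with a geometric mean
  (CRP is right-skewed, approximately log-normal).
* **Index date.** Each patient's first eligible grouped CRP sets the
  index date; SI at index means grouped value ≥ 2 mg/L.
* **Renal classification.** eGFR from serum creatinine via CKD-EPI 2021
  (142 · min(Scr/κ,1)^α · max(Scr/κ,1)^−1.200 · 0.9938^age · 1.012 if
  female); CKD = stage ≥ 3 diagnosis code, most recent prior
  eGFR < 60 mL/min/1.73 m², or UACR ≥ 30 mg/g, with KDIGO-style staging.
* **Three prevalence estimands** with Wilson intervals: SI at the first
  eligible CRP; point prevalence at the data cutoff among survivors with
  an eligible CRP in the prior 18 months; period prevalence over the whole
  study window — each stratified by CKD status/stage, sex and age band,
  plus a sensitivity analysis excluding inflammatory/rheumatoid disease.
* **Characterization tables**: baseline demographics, labs and vitals
  (most recent value within 18 months before index), comorbidity history,
  and 12-month drug-utilization windows, compared between SI groups.
* **A seeded synthetic-cohort generator** with exported ground truth, so
  the whole pipeline is testable end-to-end even though the source data
  class (licensed EHR databases) cannot be redistributed.

## Worked example

```r
library(inflaprev)

cfg <- default_run_config()
cfg$generator$n_patients <- 5000   # synthetic cohort, seed 1
res <- run_pipeline(cfg, outdir = "run", quiet = TRUE)

res$cohort
#> <ascvd_cohort>
#>                      stage    n
#> 1         identified_ascvd 5000
#> 2 after_patient_exclusions 4891
#> 3     with_crp_measurement 2789
#> 4        with_eligible_crp 2037
#>   SI at index: 1134 / 2037 (55.7%)

subset(res$estimates, stratifier == "overall" & analysis == "main",
       select = c(estimand, numerator, denominator, proportion))
#>         estimand numerator denominator proportion
#>     at_first_crp      1134        2037  0.5567010
#>  point_at_cutoff       393         720  0.5458333
#>           period      1318        2037  0.6470299
```

Reading the output: of 5,000 synthetic ASCVD patients, 4,891 survive the
age/chronic-infection exclusions, 2,789 ever had a CRP test and 2,037 had
at least one *eligible* test and enter the cohort. 55.7% of them are in the
SI phenotype at their index date; among survivors with a recent eligible
CRP at the cutoff the point prevalence is 54.6%, and 64.7% qualify at some
time during the study. CKD-stratified estimates
(`stratifier == "ckd_status"`) show the expected gradient — SI is more
common in the CKD stratum (59.4% vs 54.6% at index in this run).

Every output table (index records, eligibility exclusion log, flowchart,
estimates, baseline and utilization tables) is written under `outdir` and
listed in `manifest.json` with MD5 checksums; re-running with the same
config and seed reproduces the checksums bit for bit.

A thin CLI wraps the same functions:

```sh
exec/inflaprev simulate   --seed 7 --outdir data/
exec/inflaprev run-all    --seed 7 --outdir run/
```

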