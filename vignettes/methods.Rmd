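---
title: "Phenotyping systemic inflammation in ASCVD cohorts: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phenotyping systemic inflammation in ASCVD cohorts: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`inflaprev` turns routine primary-care event tables into a reproducible
estimate of the prevalence of systemic inflammation (SI) — C-reactive
protein (CRP) ≥ 2 mg/L — among patients with atherosclerotic
cardiovascular disease (ASCVD). This vignette explains the model behind
each stage, the parameters that matter, the numerical conventions, and
what the synthetic-data tests do and do not establish about real data.

## Why CRP needs a computable phenotype

CRP is an acute-phase reactant: a single raw measurement conflates chronic
low-grade inflammation with transient spikes from infections, drug
effects and malignancy. The phenotype therefore discards measurements
that are

1. **pre-diagnostic** — taken before the first ASCVD diagnosis (strict:
   the diagnosis day itself counts as post-diagnostic);
2. **infection-contaminated** — any value above 20 mg/L (strict), or taken
   within 2 months after or 7 days before an antibiotic/antiviral
   prescription (both ends inclusive);
3. **immunosuppressant-affected** — taken less than 3 months after an
   immunosuppressant prescription (one-sided, exclusive at 90 d);
4. **cancer-associated** — taken less than 3 years after a malignancy
   code, except non-melanoma skin cancer (exclusive at 1095 d).

Calendar units are fixed-day approximations (2 months = 60 d, 3 months =
90 d, 3 years = 1095 d, 18 months = 548 d, 12 months = 365 d), all
configurable. Fixed days make window arithmetic exactly reproducible;
calendar-month arithmetic would shift boundaries by 0–3 days depending on
the anchor month, which matters for no scientific conclusion but breaks
bit-level reproducibility. Boundary semantics follow a literal reading of
the rule statements: "within" is inclusive, "less than" is exclusive,
"> 20 mg/L" is strict, and the SI threshold "≥ 2 mg/L" is inclusive.

Each raw measurement receives exactly one exclusion label — the first
firing rule in the order above — so label counts sum to the raw count and
the attrition is fully accountable. Retention is the conjunction of all
rules, so the labelling order can never change the retained set.

### Grouping repeat measurements

Eligible measurements within 3 months are summarised by a geometric mean,
the natural location summary for a right-skewed, approximately log-normal
biomarker. The grouping algorithm is *greedy from the earliest*: the first
ungrouped measurement anchors a group holding every measurement within
90 d of it, and the group carries the anchor's date. This choice is one of
several defensible conventions (last-member or mean dates would also be
deterministic); greedy anchoring was chosen because it is order-independent
— the output is invariant to input permutation, which the test suite
checks by property — and because the anchor date gives the index date the
earliest defensible position, which is conservative for look-back windows.
A CRP of exactly 0 mg/L is rejected at parse time: the geometric mean is
undefined at zero, and 0 is below any assay floor.

The patient's first grouped record sets the **index date**; SI at index
means the grouped value is ≥ 2 mg/L. Patients with no eligible record are
excluded from the cohort (this is attrition, not an error).

## Renal classification

eGFR is computed from stored serum creatinine at classification time with
the CKD-EPI 2021 race-free equation,

$$\mathrm{eGFR} = 142 \cdot \min(\mathrm{Scr}/\kappa, 1)^{\alpha}
  \cdot \max(\mathrm{Scr}/\kappa, 1)^{-1.200} \cdot 0.9938^{\mathrm{age}}
  \cdot 1.012\,[\text{if female}]$$

with κ = 0.7 (F) / 0.9 (M) and α = −0.241 (F) / −0.302 (M), so the
equation remains the single source of truth (eGFR is never stored as a
lab). CKD at a reference date means: a stage ≥ 3 diagnosis code on or
before it, **or** most recent prior eGFR < 60 mL/min/1.73 m² (strict),
**or** most recent prior UACR ≥ 30 mg/g (inclusive). Patients with no
creatinine measurement and no CKD code are *unknown*, a stratum reported
in its own right, never merged into "no CKD".

Two deliberately exposed switches:

* `egfr_rule = "latest"` (default) implements current-status semantics —
  the most recent prior eGFR decides; `"any"` fires on any historical
  value below threshold. Point-prevalence designs want current status;
  both are tested.
* Chronicity is **not** required (no two-measurements-90-days-apart
  criterion): the sustained-abnormality requirement cannot be verified in
  sparse outpatient data without discarding most patients, so
  single-measurement semantics is implemented and documented.

Stages use half-open KDIGO bands on the same most-recent eGFR: < 15
stage 5, [15, 30) stage 4, [30, 60) stage 3; eGFR ≥ 60 with UACR ≥ 30
is stage 1/2; a diagnosis-only CKD (no eGFR) has stage *unknown*. At
exact band edges the half-open convention sends the value to the less
severe band (an eGFR of exactly 15 is stage 4).

## Cohort, estimands, characterization

Cohort entry requires ASCVD (any of four ICD-9 subtype concept sets;
subtype flags are a union over all time, so their percentages may sum
above 100%), age ≥ 18 at the index date, no chronic-infection diagnosis
ever (chronic conditions do not resolve), and ≥ 1 eligible CRP. The
attrition flowchart reports four non-increasing counts and aborts on any
internal inconsistency.

Three estimands share one estimator core:

* **at first eligible CRP** — SI-at-index over all included patients;
* **point prevalence** — among patients alive at the data cutoff with
  ≥ 1 eligible grouped CRP anchored in the prior 548 d; status comes from
  the *most recent* such record (current-status semantics again; an
  "any in window" switch exists);
* **period prevalence** — any qualifying grouped record during the study;
  by construction a superset of the index numerator, an ordering the test
  suite checks on randomized toy cohorts.

Stratified variants (CKD status — with *unknown* as a third stratum —
CKD stage, sex, age bands <65 / 65–74 / ≥75) must conserve: stratum
numerators and denominators sum to the parent's. Wilson intervals
accompany every estimate; empty strata are reported as missing, never as
zero. The sensitivity analysis recomputes all three estimands after
removing patients with any inflammatory/rheumatoid code strictly before
index.

Characterization windows: labs and vitals take the most recent value in
`[index − 548 d, index)` (strictly before index, so an on-index lab never
describes "baseline"); comorbidity history is any code strictly before
index, except the cancer flag, which requires the code **more than**
1095 d before (recent cancers were already consumed by eligibility
rule iv); drug exposure is `[index − 365 d, index)` pre and
`(index, index + 365 d]` post — the index day belongs to neither window,
avoiding double counting. Group comparisons default to chi-squared
(categorical), Welch *t* (approximately normal), and Wilcoxon rank-sum
(skewed: CRP, UACR); the test per variable is a declared choice, not an
inference, and degenerate inputs return a missing p-value. No
multiple-testing correction is applied, and the tables say so.

## The synthetic generator

Licensed EHR databases cannot ship with a package, so `inflaprev`
includes a first-class generator whose defaults *are* the study
conditions the pipeline assumes:

| parameter | default | unit | rationale |
|---|---|---|---|
| study window | 2014-01-01 – 2023-07-31 | dates | analysis window |
| `age_mean` / `age_sd` | 71 / 12 | years | ASCVD cohort age structure |
| `p_male` | 0.57 | — | cohort composition |
| `p_ckd` | 0.32 | — | CKD stratum share |
| `crp_log_median` | 2.9 / 2.2 | mg/L | CKD / non-CKD medians; the 32/68 mixture gives an overall median near 2.4 |
| `crp_log_sigma` | 1.03 | log-units | from an IQR of 1.2–4.8 around median 2.4: ln(4.8/1.2)/(2·0.6745) |
| `crp_rate_per_year` | 0.16 | tests/yr | yields ≈ two-thirds of patients with a single eligible measurement |
| `infection_rate_per_year` | 0.3 | episodes/yr | drives both antibiotic use and CRP spikes |
| `annual_mortality` | 0.05 | /yr | plausible for an elderly ASCVD cohort |

Mechanisms worth knowing:

* **Baseline CRP is truncated at 20 mg/L** (inverse-CDF truncation, ~2%
  of log-normal mass). Values above the acute cap therefore arise *only*
  from infection episodes, which makes the infection rule's recall and
  specificity exactly decidable against truth flags. An optional
  per-patient log-normal intercept (`crp_patient_intercept_sd`, default
  0.3) induces within-patient correlation; the marginal log-SD is held at
  `crp_log_sigma`. The real degree of CRP autocorrelation is unknown —
  this is an assumption, exposed as config.
* **Infection episodes couple two signals**: each emits an
  antibiotic/antiviral prescription and inflates every CRP test falling
  in `[rx − 7 d, rx + 60 d]` strictly above the cap, flagging it in the
  ground truth.
* **CKD is induced mechanistically**: a stratum-specific target eGFR is
  drawn (stage bands for the CKD stratum, ≥ 65 for the rest), perturbed
  by ~4% log-normal measurement noise per test, and *inverted through the
  CKD-EPI 2021 equation* into serum creatinine at the measurement date.
  The classifier is thereby exercised end-to-end from raw creatinine, not
  from a label. Non-CKD UACR is truncated below 30 mg/g so the truth
  stratum stays clean; a configurable fraction (9% of non-CKD) has no
  renal data at all and must surface as status *unknown*.
* **The generator keeps its own books**: per-patient true CKD stratum and
  stage, the true SI-at-first-eligible indicator (geometric mean of the
  first 90-day group of non-inflated post-diagnosis CRPs), and per-event
  infection flags, computed by simple loop-free code independent of the
  pipeline's engine.

What the generator does **not** emulate — and therefore what passing
tests do not show about real data: ICD-9 coding noise and miscoding,
correlation between comorbidities and CRP levels (baseline tables on
synthetic data show null group differences except through CKD),
treatment-response dynamics, informative CRP testing (in reality sicker
patients are tested more), and calendar trends. The synthetic cohort
validates the *machinery* — windows, grouping, classification,
accounting — not clinical effect sizes.

## Numerical and engineering choices

* Dates are ISO-8601; all arithmetic is in whole days on integer
  day counts.
* The eligibility engine is a `data.table` non-equi-join implementation;
  an independent O(n·m) pairwise brute force (plain loops over every
  CRP × event pair) must agree with it record for record — the suite
  checks 1,000 patients with dense random events, and the grouping engine
  against a scalar greedy oracle.
* Geometric means are computed as `exp(mean(log(x)))` and clamped into
  `[min(members), max(members)]` to keep the containment invariant exact
  under floating point.
* Parameter-recovery tests run 50,000 generated patients (large enough
  that three binomial standard errors are a sub-percentage-point band);
  trigger-recall runs 20 seeds at 150 patients; most structural tests use
  a few hundred patients, sizes chosen to keep the default suite fast
  while leaving the recovery bands meaningful.
* Malformed input rows (bad dates, unknown analytes, negative values) are
  rejected and counted, never silently dropped; a missing mandatory
  column aborts. Duplicate patient identifiers abort.
* `run_pipeline()` writes every output with an MD5 checksum into a
  manifest; identical configs (including the generator seed) reproduce
  identical checksums.

## Known limitations

* Code lists shipped as defaults are illustrative prefix sets; any real
  analysis must supply validated vocabularies.
* The pipeline models outpatient data only — no inpatient episodes, no
  procedure codes, no assay-type distinction (standard vs
  high-sensitivity CRP).
* Single-measurement CKD semantics (no KDIGO chronicity confirmation)
  will overcall CKD relative to a two-measurement rule in data with
  acute kidney injury episodes.
* Fixed-day calendar approximations shift window edges by up to three
  days relative to calendar-month arithmetic.
* The "34% had a CRP measurement" style of flowchart percentage depends
  on which denominator carries the patient-level exclusions; the
  flowchart reports all four counts so either convention can be derived.
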