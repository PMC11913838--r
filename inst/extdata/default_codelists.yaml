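# Illustrative default code lists mapping named clinical concepts to ICD-9
# or ATC code prefixes. These defaults cover the hierarchical ranges a
# practitioner would start from; they are NOT an authoritative, validated
# mapping — production analyses should supply their own reviewed lists.
concepts:
  # --- ASCVD subtypes (ICD-9) ---
  ascvd_coronary:
    system: ICD9
    prefixes: ["410", "411", "412", "413", "414"]
  ascvd_cerebrovascular:
    system: ICD9
    prefixes: ["433", "434", "435", "436", "437.0", "437.1", "438"]
  ascvd_pad:
    system: ICD9
    prefixes: ["440.2", "440.3", "440.4", "443.9"]
  ascvd_other:
    system: ICD9
    prefixes: ["440.0", "440.1", "440.8", "440.9", "441", "444"]
  # --- exclusions / eligibility triggers ---
  chronic_infection:
    system: ICD9
    prefixes: ["042", "010", "011", "012", "013", "014", "015", "016", "017", "018", "070"]
  malignancy:
    system: ICD9
    prefixes: ["14", "15", "16", "17", "18", "19", "200", "201", "202", "203", "204", "205", "206", "207", "208"]
  non_melanoma_skin_cancer:
    system: ICD9
    prefixes: ["173"]
  antibiotic_antiviral:
    system: ATC
    prefixes: ["J01", "J05"]
  immunosuppressant:
    system: ATC
    prefixes: ["L04A"]
  # --- renal ---
  ckd_stage3plus:
    system: ICD9
    prefixes: ["585.3", "585.4", "585.5", "585.6"]
  # --- comorbidities (ICD-9) ---
  diabetes:
    system: ICD9
    prefixes: ["250"]
  hypertension:
    system: ICD9
    prefixes: ["401", "402", "403", "404", "405"]
  copd:
    system: ICD9
    prefixes: ["490", "491", "492", "494", "496"]
  dementia:
    system: ICD9
    prefixes: ["290", "331.0"]
  heart_failure:
    system: ICD9
    prefixes: ["428"]
  atrial_fibrillation:
    system: ICD9
    prefixes: ["427.3"]
  ibd:
    system: ICD9
    prefixes: ["555", "556"]
  rheumatoid_disease:
    system: ICD9
    prefixes: ["714", "710", "720.0"]
  cns_inflammatory_disease:
    system: ICD9
    prefixes: ["340", "323"]
  liver_disease:
    system: ICD9
    prefixes: ["571"]
  inflammatory_rheumatoid:
    system: ICD9
    prefixes: ["714", "710", "720.0", "696", "555", "556", "340"]
  # --- drug classes (ATC) ---
  corticosteroids:
    system: ATC
    prefixes: ["H02AB"]
  immunosuppressants_rx:
    system: ATC
    prefixes: ["L04A"]
  antibiotics:
    system: ATC
    prefixes: ["J01"]
  antivirals:
    system: ATC
    prefixes: ["J05"]
  antimycotics:
    system: ATC
    prefixes: ["J02"]
  antiplatelet_agents:
    system: ATC
    prefixes: ["B01AC"]
  aspirin:
    system: ATC
    prefixes: ["B01AC06", "N02BA01"]
  anticoagulants:
    system: ATC
    prefixes: ["B01AA", "B01AE", "B01AF"]
  nsaids:
    system: ATC
    prefixes: ["M01A"]
  acei_arb:
    system: ATC
    prefixes: ["C09"]
  mra:
    system: ATC
    prefixes: ["C03DA"]
  beta_blockers:
    system: ATC
    prefixes: ["C07"]
  diuretics:
    system: ATC
    prefixes: ["C03"]
  calcium_channel_blockers:
    system: ATC
    prefixes: ["C08"]
  glucose_lowering:
    system: ATC
    prefixes: ["A10"]
  sglt2_inhibitors:
    system: ATC
    prefixes: ["A10BK"]
  glp1_receptor_agonists:
    system: ATC
    prefixes: ["A10BJ"]
  statins:
    system: ATC
    prefixes: ["C10AA", "C10BA", "C10BX"]
  other_lipid_lowering:
    system: ATC
    prefixes: ["C10AX", "C10AB", "C10AC", "C10AD"]
  ezetimibe:
    system: ATC
    prefixes: ["C10AX09"]
  pcsk9_inhibitors:
    system: ATC
    prefixes: ["C10AX13", "C10AX14"]
  omega3:
    system: ATC
    prefixes: ["C10AX06"]
  fibrates_resins_nicotinic:
    system: ATC
    prefixes: ["C10AB", "C10AC", "C10AD"]
  other_bp_medications:
    system: ATC
    prefixes: ["C02"]
  colchicine:
    system: ATC
    prefixes: ["M04AC01"]
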