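# Rolling-window chronic-condition classification rules for the eight
# tracked conditions. A person is classified with a condition given at
# least one hospital diagnosis (ICD-10-CA prefix) OR at least two
# physician claims (ICD-9 prefix) whose service dates differ by at most
# window_days. Depression uses a one-year window and additionally requires
# treatment evidence (antidepressant dispensation, depression claim or
# depression hospitalization) in the index year when first qualifying
# before it. Code prefixes are documented stand-ins and overridable.
conditions:
  hypertension:
    icd9: ["401", "402", "403", "404", "405"]
    icd10: ["I10", "I11", "I12", "I13", "I15"]
    window_days: 730
  diabetes:
    icd9: ["250"]
    icd10: ["E10", "E11", "E13", "E14"]
    window_days: 730
  copd:
    icd9: ["491", "492", "496"]
    icd10: ["J41", "J43", "J44"]
    window_days: 730
  osteoarthritis:
    icd9: ["715"]
    icd10: ["M15", "M16", "M17", "M18", "M19"]
    window_days: 730
  dementia:
    icd9: ["290", "294", "331"]
    icd10: ["F00", "F01", "F02", "F03", "G30"]
    window_days: 730
  depression:
    icd9: ["296", "311"]
    icd10: ["F32", "F33"]
    window_days: 365
    persistence: true
    treatment_atc: ["N06A"]
  epilepsy:
    icd9: ["345"]
    icd10: ["G40"]
    window_days: 730
  parkinsonism:
    icd9: ["332"]
    icd10: ["G20", "G21"]
    window_days: 730
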