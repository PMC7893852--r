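# Administrative frailty identification rules.
# Rule 1: resident in long-term care or assisted living during the index year.
# Rule 2: terminally ill (palliative-care coding) in the index year.
# Rule 3: at least `efs_min_indices` distinct modified-Edmonton-Frail-Scale
#         domains with a qualifying event in the index year.
# Code sets are documented stand-ins and fully overridable; prefix matching
# is dot-insensitive.
terminal_illness:
  icd9: ["V66.7"]
  icd10: ["Z51.5"]
efs_min_indices: 2
polypharmacy_min_distinct: 6
efs_domains:
  cognition:
    icd9: ["290", "294", "331"]
    icd10: ["F00", "F01", "F02", "F03", "G30"]
  mood:
    icd9: ["296", "300.0", "311"]
    icd10: ["F32", "F33", "F41"]
  incontinence:
    icd9: ["788.3", "625.6"]
    icd10: ["N39.3", "N39.4", "R32"]
  falls_mobility:
    icd9: ["E88", "719.7"]
    icd10: ["W0", "W1", "R26"]
  nutrition:
    icd9: ["783"]
    icd10: ["R63", "R64"]
  polypharmacy: distinct_atc
  functional_dependence:
    icd9: ["V46", "V49.8"]
    icd10: ["Z74", "Z99"]
  social_support:
    icd9: ["V60"]
    icd10: ["Z59", "Z60"]
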