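{
  "atoms": {
    "dementia": {"kind": "icd9_prefix", "values": ["290"]},
    "vitamins": {"kind": "atc_prefix", "values": ["A11"]},
    "furosemide": {"kind": "atc_prefix", "values": ["C03CA01"]},
    "obstruction_kw": {"kind": "text_keyword", "values": ["obstruction"]}
  },
  "expression": ["or", "dementia", ["and", "vitamins", "furosemide"], "obstruction_kw"],
  "lookback_years": 6
}
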