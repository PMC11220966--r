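{
  "name": "matscholar_guideline",
  "queries": {
    "MAT": {"strategy": "guideline", "text": "Any inorganic solid or alloy, any non-gaseous element"},
    "SPL": {"strategy": "guideline", "text": "Names for crystal structures/phases"},
    "DSC": {"strategy": "guideline", "text": "Special descriptions of the type/shape of the sample"},
    "PRO": {"strategy": "guideline", "text": "Anything measurable that can have a unit and a value"},
    "APL": {"strategy": "guideline", "text": "Any high-level application such as photovoltaics, or any specific device such as field-effect transistor"},
    "CMT": {"strategy": "guideline", "text": "Any method used to characterize a material"},
    "SMT": {"strategy": "guideline", "text": "Any technique for synthesizing a material"}
  }
}
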