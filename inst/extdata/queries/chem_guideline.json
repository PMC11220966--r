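{
  "name": "chem_guideline",
  "queries": {
    "CHEM": {"strategy": "guideline", "text": "Look up any chemical compound, drug, element or molecular entity mentioned in the text"}
  }
}
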