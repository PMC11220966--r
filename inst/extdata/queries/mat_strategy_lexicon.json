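{
  "name": "mat_strategy_lexicon",
  "entity_type": "MAT",
  "lexicon": {
    "keywords": ["inorganic material"],
    "template": "Which <kw> is mentioned in the text?",
    "wikipedia": "Materials made from inorganic substances alone or in combination with other substances",
    "synonyms": ["Inorganic material"],
    "guideline": "Look up any inorganic solids or alloys, any non-gaseous elements."
  }
}
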