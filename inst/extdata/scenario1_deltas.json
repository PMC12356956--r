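{
  "type": "risk_table",
  "note": "Two-factor worked example (impaired driving x snowy road), delta-encoded: only the deltas, not the absolute risks, are available for this scenario, so the baseline is normalised to 0 and each cell stores the delta itself. Only differences are meaningful on this scale.",
  "outcome": "accident",
  "outcome_level": "accident",
  "scale_note": "delta-encoded (baseline normalised to 0)",
  "factors": [
    {"variable": "physical_condition", "reference": "normal", "risk": "dui"},
    {"variable": "surface", "reference": "dry", "risk": "snow"}
  ],
  "values": [
    {"config": {"physical_condition": "normal", "surface": "dry"}, "risk": 0},
    {"config": {"physical_condition": "dui", "surface": "dry"}, "risk": 0.895},
    {"config": {"physical_condition": "normal", "surface": "snow"}, "risk": 0.018},
    {"config": {"physical_condition": "dui", "surface": "snow"}, "risk": 0.997}
  ]
}
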