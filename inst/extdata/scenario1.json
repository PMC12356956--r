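{
  "type": "scenario",
  "note": "Two-factor scenario over the delta-encoded table scenario1_deltas.json.",
  "outcome": "accident",
  "outcome_level": "accident",
  "factors": [
    {"variable": "physical_condition", "reference": "normal", "risk": "dui"},
    {"variable": "surface", "reference": "dry", "risk": "snow"}
  ],
  "context": {}
}
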