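{
  "type": "scenario",
  "note": "Three-factor scenario over scenario3_table3.json.",
  "outcome": "severity",
  "outcome_level": "fatal",
  "factors": [
    {"variable": "physical_condition", "reference": "normal", "risk": "dui"},
    {"variable": "surface", "reference": "dry", "risk": "snow"},
    {"variable": "safety_equipment", "reference": "belt", "risk": "none"}
  ],
  "context": {}
}
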