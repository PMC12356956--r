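{
  "type": "scenario",
  "note": "Two-factor with-belt scenario over scenario3_table3.json: impaired driving and snowy road with the seatbelt worn (safety_equipment pinned at its reference level via the context).",
  "outcome": "severity",
  "outcome_level": "fatal",
  "factors": [
    {"variable": "physical_condition", "reference": "normal", "risk": "dui"},
    {"variable": "surface", "reference": "dry", "risk": "snow"}
  ],
  "context": {"safety_equipment": "belt"}
}
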