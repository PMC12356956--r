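{
  "type": "risk_table",
  "note": "Three-factor worked example (impaired driving x snowy road x no seatbelt): reference fatal-accident risk values on a percentage-type scale (values exceed 1). Contains the baseline, the three single-risk configurations, the all-risk configuration, and the two-risk-with-belt configuration. Other two-risk configurations are not part of the worked example and are absent.",
  "outcome": "severity",
  "outcome_level": "fatal",
  "scale_note": "percentage-scale fatal-accident risk",
  "factors": [
    {"variable": "physical_condition", "reference": "normal", "risk": "dui"},
    {"variable": "surface", "reference": "dry", "risk": "snow"},
    {"variable": "safety_equipment", "reference": "belt", "risk": "none"}
  ],
  "values": [
    {"config": {"physical_condition": "normal", "surface": "dry", "safety_equipment": "belt"}, "risk": 0.259},
    {"config": {"physical_condition": "dui", "surface": "dry", "safety_equipment": "belt"}, "risk": 0.277},
    {"config": {"physical_condition": "normal", "surface": "snow", "safety_equipment": "belt"}, "risk": 0.273},
    {"config": {"physical_condition": "normal", "surface": "dry", "safety_equipment": "none"}, "risk": 4.793},
    {"config": {"physical_condition": "dui", "surface": "snow", "safety_equipment": "none"}, "risk": 5.193},
    {"config": {"physical_condition": "dui", "surface": "snow", "safety_equipment": "belt"}, "risk": 0.297}
  ]
}
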