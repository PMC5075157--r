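{
  "provenance": "Two-by-two event counts reported by a published external validation of the IMPACT rule in a large US commercial/Medicare claims cohort of 47,531 adult PE hospitalizations; orientation: positive prediction = high-risk",
  "cohort_n": 47531,
  "low_risk_n": 9259,
  "high_risk_n": 38272,
  "panels": {
    "in_hospital_death": { "tp": 3585, "fp": 34687, "tn": 9077, "fn": 182 },
    "death_30d":         { "tp": 4259, "fp": 34013, "tn": 9076, "fn": 183 },
    "composite_30d":     { "tp": 8741, "fp": 29531, "tn": 8130, "fn": 1129 }
  }
}
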