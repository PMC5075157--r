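{
  "intercept": -5.833,
  "age_per_year": 0.026,
  "terms": {
    "myocardial_infarction": 0.402,
    "chronic_lung_disease": 0.368,
    "stroke": 0.464,
    "prior_major_bleeding": 0.638,
    "atrial_fibrillation": 0.298,
    "cognitive_impairment": 1.061,
    "heart_failure": 0.554,
    "renal_failure": 0.364,
    "liver_disease": 0.484,
    "coagulopathy": 0.523,
    "cancer": 1.068
  },
  "low_risk_threshold": 0.015,
  "provenance": "Published IMPACT derivation coefficients (log-odds); threshold is the conventional 1.5 percent low-risk cut-off"
}
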