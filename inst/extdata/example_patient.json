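{
  "description": "Worked-example patient: 65-year-old non-Hispanic black man, BP 140/90 mm Hg, 1 BP medication, former smoker, no aspirin, on a statin; labs in conventional units (mg/dl).",
  "units": "conventional",
  "patient": {
    "age": 65,
    "female": 0,
    "black": 1,
    "hispanic": 0,
    "sbp": 140,
    "dbp": 90,
    "n_bp_agents": 1,
    "current_smoker": 0,
    "former_smoker": 1,
    "aspirin": 0,
    "statin": 1,
    "creatinine": 1.1,
    "total_chol": 190,
    "hdl": 50,
    "triglycerides": 120,
    "bmi": 30
  }
}
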