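{
  "name": "sprint_benefit",
  "version": "1.0",
  "outcome": "cvd",
  "direction": "benefit",
  "horizon": 5,
  "s0": 0.943,
  "lbar": 6.766,
  "units": "conventional",
  "coef_main": {
    "age": 0.060,
    "female": -0.117,
    "black": -0.058,
    "hispanic": -0.309,
    "sbp": 0.008,
    "dbp": 0.002,
    "n_bp_agents": 0.169,
    "current_smoker": 0.761,
    "former_smoker": 0.139,
    "aspirin": 0.129,
    "statin": 0.157,
    "creatinine": 0.581,
    "total_chol": 0.004,
    "hdl": -0.013,
    "triglycerides": 0.0004,
    "bmi": 0.010
  },
  "coef_treatment": 1.400,
  "coef_interaction": {
    "age": -0.012,
    "black": -0.098,
    "dbp": -0.009,
    "current_smoker": 0.207,
    "hdl": -0.0009,
    "triglycerides": -0.001
  },
  "coef_main_si": {
    "age": 0.060,
    "female": -0.117,
    "black": -0.058,
    "hispanic": -0.309,
    "sbp": 0.008,
    "dbp": 0.002,
    "n_bp_agents": 0.169,
    "current_smoker": 0.761,
    "former_smoker": 0.139,
    "aspirin": 0.129,
    "statin": 0.157,
    "creatinine": 0.00657,
    "total_chol": 0.155,
    "hdl": -0.500,
    "triglycerides": 0.034,
    "bmi": 0.010
  },
  "coef_interaction_si": {
    "age": -0.012,
    "black": -0.098,
    "dbp": -0.009,
    "current_smoker": 0.207,
    "hdl": -0.035,
    "triglycerides": -0.086
  },
  "example": {
    "raw_intensive": 6.251,
    "raw_standard": 6.704,
    "risk_intensive": 0.0345,
    "risk_standard": 0.0537,
    "difference": 0.0192
  }
}
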