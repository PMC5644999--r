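{
  "name": "sprint_harm",
  "version": "1.0",
  "outcome": "sae",
  "direction": "harm",
  "horizon": 5,
  "s0": 0.897,
  "lbar": 4.343,
  "units": "conventional",
  "coef_main": {
    "age": 0.033,
    "female": 0.144,
    "hispanic": -0.545,
    "sbp": 0.010,
    "dbp": -0.008,
    "n_bp_agents": 0.182,
    "current_smoker": 0.484,
    "former_smoker": 0.091,
    "aspirin": 0.047,
    "statin": -0.136,
    "creatinine": 0.780,
    "total_chol": -0.006,
    "hdl": 0.008,
    "triglycerides": 0.0001
  },
  "coef_treatment": -0.803,
  "coef_interaction": {
    "female": -0.017,
    "current_smoker": 0.094,
    "statin": 0.286,
    "creatinine": 0.037,
    "total_chol": 0.004,
    "triglycerides": 0.001
  },
  "coef_main_si": {
    "age": 0.033,
    "female": 0.144,
    "hispanic": -0.545,
    "sbp": 0.010,
    "dbp": -0.008,
    "n_bp_agents": 0.182,
    "current_smoker": 0.484,
    "former_smoker": 0.091,
    "aspirin": 0.047,
    "statin": -0.136,
    "creatinine": 0.00883,
    "total_chol": -0.213,
    "hdl": 0.311,
    "triglycerides": 0.00643
  },
  "coef_interaction_si": {
    "female": -0.017,
    "current_smoker": 0.094,
    "statin": 0.286,
    "creatinine": 0.000422,
    "total_chol": 0.172,
    "triglycerides": 0.078
  },
  "example": {
    "raw_intensive": 3.688,
    "raw_standard": 3.213,
    "risk_intensive": 0.0549,
    "risk_standard": 0.0345,
    "difference": 0.0204
  },
  "notes": "The printed 3-decimal coefficients do not exactly reproduce the printed per-row contributions (rounding in the source table); exactness checks for this score go through the printed raw scores."
}
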