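{
  "name": "accord_benefit",
  "version": "1.0",
  "inherits": "sprint_benefit",
  "outcome": "cvd",
  "direction": "benefit",
  "horizon": 5,
  "s0": 0.881,
  "lbar": 2.110,
  "notes": "SPRINT-derived coefficients with the baseline survival and centering constant recomputed on the ACCORD-BP cohort (type 2 diabetes); coefficients identical to sprint_benefit."
}
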