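{
  "name": "accord_harm",
  "version": "1.0",
  "inherits": "sprint_harm",
  "outcome": "sae",
  "direction": "harm",
  "horizon": 5,
  "s0": 0.887,
  "lbar": 3.980,
  "notes": "SPRINT-derived coefficients with the baseline survival and centering constant recomputed on the ACCORD-BP cohort (type 2 diabetes); coefficients identical to sprint_harm."
}
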