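# Default factorial scenario grid: 2 control-arm risks x 2 treatment RRs x
# 2 prognostic-factor RRs. Run-level fields may be overridden by the caller.
scenarios:
  - {id: 1, baseline_risk: 0.10, treatment_rr: 0.75, pf_rr: 5}
  - {id: 2, baseline_risk: 0.10, treatment_rr: 0.75, pf_rr: 2}
  - {id: 3, baseline_risk: 0.10, treatment_rr: 1.00, pf_rr: 5}
  - {id: 4, baseline_risk: 0.10, treatment_rr: 1.00, pf_rr: 2}
  - {id: 5, baseline_risk: 0.05, treatment_rr: 0.75, pf_rr: 5}
  - {id: 6, baseline_risk: 0.05, treatment_rr: 0.75, pf_rr: 2}
  - {id: 7, baseline_risk: 0.05, treatment_rr: 1.00, pf_rr: 5}
  - {id: 8, baseline_risk: 0.05, treatment_rr: 1.00, pf_rr: 2}
settings: [unconditional, conditional]
# lambda_grid: omitted -> setting-specific defaults (14 values unconditional,
# 11 values conditional)
n_grid: [25, 50, 125, 500, 1000, 2000]
n_replicates: 10000
base_seed: 20120401
d1_thresholds: [0.005, 0.01, 0.025, 0.05, 0.10, 0.15, 0.20]
d2_thresholds: [0, 0.05, 0.10, 0.15, 0.20, 0.25]
models: [unadjusted, adjusted]
replicate_dump: false
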