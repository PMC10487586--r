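# Base-case inputs for the pharmacist-adherence cost-effectiveness model.
# All monetary values are 2023 USD; cycles are two months; the horizon is
# one year (six cycles).
stage_values:
  utility: {A: 0.83, B: 0.34, C: 0.03}
  cycle_cost: {A: 22, B: 104, C: 134}
  intervention_cycle_cost: 290
model_spec:
  n_cycles: 6
  qaly_convention: per_cycle_sum
  discount_rate: 0
  death_probability_override: 0.005
thresholds:
  gdp_per_capita: 1658
  multipliers: [1, 3]
  exchange_rate: 270
calibration_targets:
  intervention: {qaly_units: 4.05, cost: 1979}
  comparator: {qaly_units: 2.93, cost: 429}
psa:
  n_iterations: 1000
seed: 1
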