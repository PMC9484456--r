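# Example cortsim run configuration.
# Omitted blocks fall back to package defaults; unknown keys are rejected.
population:
  means:
    time_to_max: 30.0
  sds:
    time_to_max: 5.0
  correlation:
    - {param1: time_to_max, param2: max_value, rho: -0.6}
expression:
  fidelity: 0.8
  mode: convex
design:
  kind: fixed
  fixed_times: [1.0, 15.0, 30.0]
assay:
  error_sd: 1.0
fitness:
  variance_share:
    max_value: 0.8
  unmeasured_share: 0.2
n_individuals: 40
n_events: 3
seed: 2024
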