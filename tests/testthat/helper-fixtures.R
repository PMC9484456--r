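# Shared fixtures; everything is generated in code.

example_params <- function() {
  response_params(baseline = 5, onset_delay = 3, time_to_max = 30,
                  max_value = 25, plateau_duration = 10,
                  return_duration = 20, end_value = 6)
}

# small cohort + fixed-time dataset used across repeatability tests
small_dataset <- function(n = 20, n_events = 2, fidelity = 1, error_sd = 0,
                          times = c(1, 15, 30), seed = 42) {
  ch <- sample_population(default_population(), n, seed = seed)
  simulate_dataset(ch, expr = expression_spec(fidelity),
                   design = sampling_design("fixed", fixed_times = times),
                   assay = assay_model(error_sd), n_events = n_events,
                   seed = seed + 1)
}
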