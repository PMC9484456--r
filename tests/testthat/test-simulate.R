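test_that("dataset dimensions follow cohort x events x samples", {
  ds <- small_dataset(n = 20, n_events = 1, times = c(1, 30, 60))
  expect_equal(nrow(ds$observed), 60)
  expect_equal(nrow(ds$truth_events), 20)
  expect_equal(dim(ds$curves), c(20, 121))
  ch <- ds$truth_individuals
  expect_error(simulate_dataset(ch, n_events = 0), "n_events")
})

test_that("simulation is deterministic given the master seed", {
  a <- small_dataset(seed = 77)
  b <- small_dataset(seed = 77)
  expect_identical(a$observed, b$observed)
  expect_identical(a$curves, b$curves)
})

test_that("changing the assay stream does not perturb expressed curves", {
  ch <- sample_population(default_population(), 8, seed = 30)
  des <- sampling_design("fixed", fixed_times = c(1, 15, 30))
  quiet <- simulate_dataset(ch, design = des, assay = assay_model(0),
                            n_events = 2, seed = 31)
  noisy <- simulate_dataset(ch, design = des, assay = assay_model(3),
                            n_events = 2, seed = 31)
  expect_identical(quiet$truth_events, noisy$truth_events)
  expect_identical(quiet$curves, noisy$curves)
  expect_false(identical(quiet$observed$value, noisy$observed$value))
})

test_that("perfect fidelity and no noise make repeated events identical", {
  ds <- small_dataset(n = 6, n_events = 3, fidelity = 1, error_sd = 0)
  per_event <- split(ds$observed$value, ds$observed$event_id)
  expect_equal(per_event[[1]], per_event[[2]])
  expect_equal(per_event[[1]], per_event[[3]])
})

test_that("fitness shares must sum to one and validate", {
  expect_error(fitness_spec(c(max_value = 0.8), 0.3), "sum to 1")
  expect_error(fitness_spec(c(max_value = 1.4), -0.4), "\\[0, 1\\]")
  expect_error(fitness_spec(c(nope = 0.5), 0.5), "parameter names")
})

test_that("fitness variance decomposition matches the configured shares", {
  ch <- sample_population(default_population(), 10000, seed = 32)
  f <- assign_fitness(ch, fitness_spec(c(max_value = 0.8), 0.2), seed = 33)
  r2 <- summary(lm(f$fitness ~ log(ch$max_value)))$r.squared
  expect_equal(r2, 0.8, tolerance = 0.02)
  # only unmeasured traits: independent of every parameter
  f0 <- assign_fitness(ch, fitness_spec(c(), 1), seed = 34)
  x <- cortsim:::cohort_matrix(ch, "sampling")
  expect_lt(max(abs(cor(f0$fitness, x))), 0.05)
  # sole deterministic driver: rank correlation 1 with the true maximum
  f1 <- assign_fitness(ch, fitness_spec(c(max_value = 1), 0), seed = 35)
  expect_equal(cor(f1$fitness, ch$max_value, method = "spearman"), 1)
})

test_that("fitness with zero-variance parameter share is rejected", {
  spec <- population_spec(sds = c(max_value = 0))
  ch <- sample_population(spec, 10, seed = 36)
  expect_error(assign_fitness(ch, fitness_spec(c(max_value = 1), 0)),
               "zero variance")
})
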