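test_that("full fidelity reproduces the true parameters exactly", {
  pop <- default_population()
  ch <- sample_population(pop, 200, seed = 5)
  ts <- cortsim:::cohort_matrix(ch, "sampling")
  set.seed(6)
  e <- cortsim:::express_matrix(ts, expression_spec(1), pop)
  expect_equal(e, cortsim:::cohort_matrix(ch), tolerance = 1e-12)
  # single-event wrapper
  p <- example_params()
  set.seed(7)
  expect_equal(unlist(express_event(p, expression_spec(1), pop)), unlist(p))
})

test_that("zero fidelity decouples expression from the true phenotype", {
  pop <- default_population()
  ch <- sample_population(pop, 10000, seed = 8)
  ts <- cortsim:::cohort_matrix(ch, "sampling")
  set.seed(9)
  e <- cortsim:::express_matrix(ts, expression_spec(0), pop)
  expect_lt(abs(cor(log(e[, "max_value"]), ts[, "max_value"])), 0.05)
  expect_lt(abs(cor(e[, "time_to_max"], ts[, "time_to_max"])), 0.05)
})

test_that("variance-preserving mixing keeps the population marginal SD", {
  pop <- default_population()
  ch <- sample_population(pop, 10000, seed = 10)
  ts <- cortsim:::cohort_matrix(ch, "sampling")
  for (w in c(0.3, 0.8)) {
    set.seed(11)
    e <- cortsim:::express_matrix(ts, expression_spec(w, "variance_preserving"),
                                  pop)
    expect_equal(sd(log(e[, "max_value"])), 0.3, tolerance = 0.02)
    expect_equal(sd(e[, "time_to_max"]), 5, tolerance = 0.15)
  }
})

test_that("convex mixing shrinks marginal variance by w^2 + (1-w)^2", {
  pop <- default_population()
  ch <- sample_population(pop, 10000, seed = 12)
  ts <- cortsim:::cohort_matrix(ch, "sampling")
  set.seed(13)
  e <- cortsim:::express_matrix(ts, expression_spec(0.6), pop)
  expect_equal(sd(e[, "time_to_max"]), 5 * sqrt(0.6^2 + 0.4^2),
               tolerance = 0.15)
})

test_that("expression mixing preserves the population correlation structure", {
  pop <- scenario_covariation_population(-0.6)
  ch <- sample_population(pop, 10000, seed = 14)
  ts <- cortsim:::cohort_matrix(ch, "sampling")
  for (mode in c("convex", "variance_preserving")) {
    set.seed(15)
    e <- cortsim:::express_matrix(ts, expression_spec(0.7, mode), pop)
    expect_equal(cor(e[, "time_to_max"], log(e[, "max_value"])), -0.6,
                 tolerance = 0.05)
  }
})

test_that("sampling designs produce times with the right support", {
  fixed <- sampling_design("fixed", fixed_times = c(1, 15, 30))
  tl <- sample_times(fixed, 5, seed = 16)
  expect_true(all(vapply(tl, identical, logical(1), c(1, 15, 30))))

  unif <- sampling_design("uniform_random", window = c(1, 60), n_samples = 3)
  tu <- unlist(sample_times(unif, 500, seed = 17))
  expect_true(all(tu >= 1 & tu <= 60))
  expect_true(all(vapply(sample_times(unif, 5, seed = 18),
                         function(t) !is.unsorted(t), logical(1))))

  wt <- sampling_design("weighted_normal", center = 32, spread = 9,
                        n_samples = 1)
  tw <- unlist(sample_times(wt, 10000, seed = 19))
  expect_true(all(tw >= 0 & tw <= 120))
  expect_equal(mean(tw), 32, tolerance = 0.3)
  expect_equal(sd(tw), 9, tolerance = 0.3)

  expect_error(sampling_design("uniform_random", window = c(5, 5)), "window")
  expect_error(sample_times(fixed, 3, t_end = 20), "t_end")
})

test_that("observation is exact without noise and calibrated with it", {
  cv <- build_curve(example_params())
  expect_equal(observe(cv, c(1, 15, 30), assay_model(0)),
               curve_value(cv, c(1, 15, 30)))
  flat <- build_curve(response_params(7, 1, 2, 7, 0, 1, 7), t_end = 60)
  expect_equal(observe(flat, c(3, 10, 50), assay_model(0)), rep(7, 3),
               tolerance = 1e-10)
  set.seed(20)
  m <- observe(cv, rep(30, 10000), assay_model(2))
  expect_equal(sd(m), 2, tolerance = 0.06)
  expect_true(all(observe(flat, rep(1, 1000), assay_model(50)) >= 0))
})
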