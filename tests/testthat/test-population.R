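test_that("identical spec, n and seed reproduce the cohort exactly", {
  spec <- default_population()
  a <- sample_population(spec, 50, seed = 9)
  b <- sample_population(spec, 50, seed = 9)
  expect_identical(a, b)
  c <- sample_population(spec, 50, seed = 10)
  expect_false(identical(a$max_value, c$max_value))
})

test_that("zero SDs collapse the population onto the (back-transformed) means", {
  spec <- population_spec(sds = stats::setNames(rep(0, 7),
                                                cortsim:::PARAM_NAMES))
  ch <- sample_population(spec, 5, seed = 1)
  expect_equal(ch$baseline, rep(5, 5))
  expect_equal(ch$max_value, rep(25, 5))  # exp(log(25))
  expect_equal(ch$time_to_max, rep(30, 5))
})

test_that("marginals and correlations are recovered at large n", {
  spec <- scenario_covariation_population(-0.6)
  ch <- sample_population(spec, 10000, seed = 2)
  # law-of-large-numbers bound, 3 sigma
  expect_lt(abs(mean(log(ch$max_value)) - log(25)), 3 * 0.3 / sqrt(10000))
  expect_equal(sd(log(ch$max_value)), 0.3, tolerance = 0.03)
  expect_equal(mean(ch$time_to_max), 30, tolerance = 0.2)
  expect_equal(cor(ch$time_to_max, log(ch$max_value)), -0.6,
               tolerance = 0.03)
  # every drawn individual satisfies the curve invariants
  x <- cortsim:::cohort_matrix(ch)
  expect_true(all(cortsim:::validate_params(x)))
})

test_that("correlation matrix validation names problems and repairs rounding", {
  r <- diag(7)
  r[1, 2] <- r[2, 1] <- 1.5
  expect_error(population_spec(correlation = r), "\\[-1, 1\\]")
  r <- diag(7)
  r[1, 2] <- 0.3
  expect_error(population_spec(correlation = r), "symmetric")
  # indefinite matrix (three mutually exclusive strong correlations)
  spec_bad <- try(population_spec(
    correlation = {
      m <- diag(7)
      m[1, 2] <- m[2, 1] <- 0.9
      m[1, 3] <- m[3, 1] <- 0.9
      m[2, 3] <- m[3, 2] <- -0.9
      m
    }), silent = TRUE)
  expect_s3_class(spec_bad, "try-error")
  expect_match(attr(spec_bad, "condition")$message, "positive semidefinite")
  # sd = 0 rows must be uncorrelated
  m <- diag(7)
  m[3, 4] <- m[4, 3] <- 0.5
  expect_error(
    population_spec(sds = c(time_to_max = 0), correlation = m),
    "sd = 0")
})

test_that("impossible populations fail with a rejection-rate error", {
  # mean time-to-max below the onset delay: most draws invalid
  spec <- population_spec(means = c(time_to_max = 2),
                          sds = c(time_to_max = 4))
  expect_error(sample_population(spec, 100, seed = 3), "50%")
})

test_that("log-scale flag produces right-skewed marginals on the natural scale", {
  ch <- sample_population(default_population(), 5000, seed = 4)
  m <- ch$max_value
  skew <- mean((m - mean(m))^3) / sd(m)^3
  expect_gt(skew, 0.5)  # log-normal sigma = 0.3 has skewness ~0.95
  expect_true(all(m > 0))
})
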