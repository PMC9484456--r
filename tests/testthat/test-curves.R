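test_that("turning points follow the seven-parameter construction", {
  tp <- turning_points(example_params())
  expect_equal(tp$time, c(0, 3, 30, 40, 60))
  expect_equal(tp$value, c(5, 5, 25, 25, 6))
  expect_true(all(diff(tp$time) > 0))
})

test_that("invalid parameters are rejected naming the offending field", {
  expect_error(response_params(-1, 3, 30, 25, 10, 20, 6), "baseline")
  expect_error(response_params(5, 3, 30, 2, 10, 20, 6), "max_value")
  expect_error(response_params(5, 31, 30, 25, 10, 20, 6), "onset_delay")
  expect_error(response_params(5, 3, 30, 25, -1, 20, 6), "plateau_duration")
  expect_error(response_params(5, 3, 30, 25, 10, 0, 6), "return_duration")
  expect_error(response_params(5, 3, 30, 25, 10, 20, NA), "non-finite")
  # onset at 0 collapses the first two turning points
  expect_error(turning_points(response_params(5, 0, 30, 25, 10, 20, 6)),
               "onset_delay")
})

test_that("turning points shift weakly rightward with each time parameter", {
  base <- c(baseline = 5, onset_delay = 3, time_to_max = 30, max_value = 25,
            plateau_duration = 10, return_duration = 20, end_value = 6)
  t0 <- turning_points(do.call(response_params, as.list(base)))$time
  for (p in c("onset_delay", "time_to_max", "plateau_duration",
              "return_duration")) {
    bumped <- base
    bumped[p] <- bumped[p] + 4
    t1 <- turning_points(do.call(response_params, as.list(bumped)))$time
    expect_true(all(t1 >= t0), info = p)
  }
})

test_that("pre-smoothing interpolation is linear and curves stay valid", {
  p <- example_params()
  # midpoint of the rise
  expect_equal(cortsim:::raw_curve_value(p, (3 + 30) / 2), (5 + 25) / 2)
  # values beyond the last turning point are held at the recovery level
  expect_equal(cortsim:::raw_curve_value(p, 100), 6)
  cv <- build_curve(p)
  expect_length(cv$values, length(cv$times))
  expect_true(all(cv$values >= 0))
})

test_that("a flat response stays exactly flat through the smoother", {
  flat <- response_params(7, 1, 2, 7, 0, 1, 7)
  cv <- build_curve(flat, t_end = 60)
  expect_equal(cv$values, rep(7, 61), tolerance = 1e-10)
})

test_that("smoothed curve peaks near the true maximum (frozen regression)", {
  cv <- build_curve(example_params())
  expect_equal(max(cv$values), 23.40048, tolerance = 1e-5)
  expect_equal(cv$times[which.max(cv$values)], 34)
  # within 10% of M and 5 min of the peak time
  expect_gt(max(cv$values), 0.9 * 25)
  expect_lte(abs(cv$times[which.max(cv$values)] - 30), 5)
})

test_that("extending t_end does not change the curve away from the old edge", {
  p <- example_params()
  short <- build_curve(p, t_end = 120)
  long <- build_curve(p, t_end = 240)
  interior <- 1:80  # clear of the shorter grid's boundary bandwidth
  expect_equal(short$values[interior], long$values[interior])
})

test_that("build_curve validates its inputs", {
  expect_error(build_curve(example_params(), t_end = 0), "t_end")
  expect_error(build_curve(example_params(), smooth_span = 0), "smooth_span")
  expect_error(build_curve(example_params(), smooth_span = 1.5), "smooth_span")
})

test_that("auc matches trapezoid geometry in both modes", {
  # constant profile
  expect_equal(auc(c(0, 5, 20), rep(3, 3), mode = "ground"), 60)
  expect_equal(auc(c(0, 5, 20), rep(3, 3), mode = "increase"), 0)
  # triangle
  expect_equal(auc(c(0, 10, 20), c(0, 10, 0), mode = "ground"), 100)
  expect_error(auc(0, 1), "2 points")
  expect_error(auc(c(0, 0), c(1, 2)), "strictly increasing")
})

test_that("auc identities: mode difference and additivity over windows", {
  set.seed(7)
  for (i in 1:10) {
    t <- sort(sample(0:100, 12))
    v <- runif(12, 0, 30)
    g <- auc(t, v, "ground")
    inc <- auc(t, v, "increase")
    expect_equal(g - inc, v[1] * (t[12] - t[1]))
    # additivity over abutting windows
    expect_equal(auc(t[1:6], v[1:6], "ground") + auc(t[6:12], v[6:12], "ground"),
                 g)
  }
})

test_that("curve_value interpolates and rejects out-of-grid times", {
  cv <- build_curve(example_params())
  expect_equal(curve_value(cv, 15.5),
               mean(cv$values[cv$times %in% c(15, 16)]))
  expect_error(curve_value(cv, 121), "outside")
  expect_error(curve_value(cv, -1), "outside")
})
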