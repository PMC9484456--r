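test_that("icc recovers the textbook cases", {
  # duplicated events, distinct individuals: perfect repeatability
  expect_equal(icc(c(0, 0, 10, 10), c("a", "a", "b", "b")), 1)
  ds_vals <- rep(1:5, each = 3)
  expect_equal(icc(ds_vals, rep(letters[1:5], each = 3)), 1)
  # i.i.d. values ignoring individual: repeatability near zero
  set.seed(40)
  v <- rnorm(400)
  suppressWarnings(r <- icc(v, rep(1:200, each = 2)))
  expect_lt(r, 0.1)
  # degenerate: no variance at all
  expect_warning(r0 <- icc(rep(3, 6), rep(1:3, each = 2)), "undefined")
  expect_true(is.nan(r0))
  expect_error(icc(1:4, 1:4), "single event")
  expect_error(icc(1:2, c(1, 1)), "2 individuals")
})

test_that("icc bootstrap attaches a CI that brackets the estimate", {
  set.seed(41)
  v <- rep(rnorm(30, sd = 3), each = 4) + rnorm(120)
  r <- icc(v, rep(1:30, each = 4), n_boot = 200)
  ci <- attr(r, "ci")
  expect_length(ci, 2)
  expect_lte(ci[1], as.numeric(r) + 1e-9)
  expect_gte(ci[2], as.numeric(r) - 1e-9)
})

test_that("profile repeatability separates consistent from inconsistent profiles", {
  # identical repeated profiles per individual, different across individuals
  obs <- tidyr::expand_grid(individual_id = 1:6, event_id = 1:2,
                            time_min = c(1, 15, 30))
  obs$value <- obs$individual_id * 2 + obs$time_min / 10
  expect_equal(profile_repeatability(obs), 1)
  # everyone identical: undefined with a warning
  obs$value <- obs$time_min
  expect_warning(r <- profile_repeatability(obs), "undefined")
  expect_true(is.nan(r))
  # mismatched grids are rejected
  bad <- obs
  bad$time_min[1] <- 2
  expect_error(profile_repeatability(bad), "same\\s+fixed times")
})

test_that("high-fidelity datasets have higher profile repeatability than zero-fidelity", {
  hi <- small_dataset(n = 30, n_events = 3, fidelity = 0.9, error_sd = 0,
                      seed = 50)
  lo <- small_dataset(n = 30, n_events = 3, fidelity = 0, error_sd = 0,
                      seed = 50)
  expect_gt(profile_repeatability(hi), profile_repeatability(lo))
})

test_that("auc repeatability bases agree when the observed points are the grid", {
  ds <- small_dataset(n = 10, n_events = 2, fidelity = 0.7, error_sd = 0,
                      times = 0:120, seed = 51)
  for (m in c("ground", "increase")) {
    full <- auc_repeatability(ds, m, "full_curve")
    obsv <- auc_repeatability(ds, m, "observed_points")
    wind <- auc_repeatability(ds, m, "windowed_curve")
    expect_equal(obsv, wind, tolerance = 1e-12)
    expect_equal(obsv, full, tolerance = 1e-12)
  }
})

test_that("ground-mode AUC is at least as repeatable as increase-mode", {
  # between-individual baseline variance is shared by every sample of an
  # individual; subtracting the first sample (increase mode) removes it
  ds <- small_dataset(n = 40, n_events = 3, fidelity = 0.8, error_sd = 0,
                      seed = 52)
  expect_gte(auc_repeatability(ds, "ground", "full_curve"),
             auc_repeatability(ds, "increase", "full_curve"))
})

test_that("plain long tables work for observed-points AUC and error paths", {
  ds <- small_dataset(n = 8, n_events = 2, seed = 53)
  tbl <- ds$observed
  expect_equal(auc_repeatability(tbl, "ground", "observed_points"),
               auc_repeatability(ds, "ground", "observed_points"))
  expect_error(auc_repeatability(tbl, "ground", "full_curve"),
               "stored event curves")
  one_pt <- tbl[tbl$time_min == 1, ]
  expect_error(auc_repeatability(one_pt, "ground", "observed_points"),
               "fewer than 2")
})

test_that("assay noise lowers per-timepoint repeatability", {
  quiet <- small_dataset(n = 40, n_events = 3, fidelity = 0.8, error_sd = 0,
                         seed = 54)
  noisy <- small_dataset(n = 40, n_events = 3, fidelity = 0.8, error_sd = 4,
                         seed = 54)
  r_q <- repeatability_report(quiet)
  r_n <- repeatability_report(noisy)
  expect_gt(mean(r_q$per_time$icc), mean(r_n$per_time$icc))
})

test_that("repeatability report covers all variants and sizes", {
  ds <- small_dataset(n = 12, n_events = 2, seed = 55)
  r <- repeatability_report(ds)
  expect_equal(nrow(r$auc), 6)
  expect_equal(r$n_individuals, 12)
  expect_equal(r$n_events, 24)
  expect_equal(r$per_time$time_min, c(1, 15, 30))
  expect_true(all(r$auc$repeatability >= 0 & r$auc$repeatability <= 1))
})
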