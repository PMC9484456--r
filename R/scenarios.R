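## Per-cell seeds derived from a scenario master seed.
cell_seed <- function(seed, i) {
  as.integer(((as.numeric(seed) + 7) * 69069 + i * 100003) %% 2147483647)
}

resolve_seed <- function(seed) {
  if (is.null(seed)) sample.int(2147483646L, 1) else as.integer(seed)
}

#' Accuracy of a single-timepoint measure of maximum glucocorticoids
#'
#' Sweeps the population-average peak time and the between-individual SDs
#' of the maximum level and of the time to reach it, holding every other
#' parameter identical across individuals. For each grid cell, `n`
#' individuals are simulated (one event each, moderate within-individual
#' variability and a small amount of assay error), observed once at
#' `sample_time`, and the R-squared of a regression of the observed value
#' on the true maximum is recorded.
#'
#' @param peak_means population-average peak times to sweep (min).
#' @param max_sd_grid SDs of the maximum level to sweep (ng/µl; the
#'   maximum is sampled on the linear scale here so these SDs apply
#'   exactly).
#' @param speed_sd_grid SDs of the time-to-maximum to sweep (min).
#' @param n individuals per cell.
#' @param sample_time the single observation time (min).
#' @param fidelity expression fidelity applied to all parameters.
#' @param error_sd assay noise SD (ng/µl).
#' @param seed master seed (one per-cell child seed is derived and
#'   reported).
#' @return Tibble with one row per cell: `peak_mean`, `max_sd`, `speed_sd`,
#'   `r_squared`, `n`, `seed`. Cells with zero variance in the true
#'   maximum report `NA` with a warning.
#' @export
scenario_peak_timing_sweep <- function(peak_means = c(15, 30, 45),
                                       max_sd_grid = c(1, 4, 8, 12),
                                       speed_sd_grid = c(1, 7, 13, 20),
                                       n = 200, sample_time = 30,
                                       fidelity = 0.8, error_sd = 1,
                                       seed = NULL) {
  stopifnot(length(peak_means) > 0, length(max_sd_grid) > 0,
            length(speed_sd_grid) > 0)
  seed <- resolve_seed(seed)
  cells <- tidyr::expand_grid(peak_mean = peak_means, max_sd = max_sd_grid,
                              speed_sd = speed_sd_grid)
  design <- sampling_design("fixed", fixed_times = sample_time)
  expr <- expression_spec(fidelity)
  assay <- assay_model(error_sd)
  cells$seed <- vapply(seq_len(nrow(cells)), cell_seed, integer(1),
                       seed = seed)
  cells$r_squared <- vapply(seq_len(nrow(cells)), function(i) {
    pop <- population_spec(
      means = c(time_to_max = cells$peak_mean[i], max_value = 25),
      sds = c(baseline = 0, onset_delay = 0,
              time_to_max = cells$speed_sd[i], max_value = cells$max_sd[i],
              plateau_duration = 0, return_duration = 0, end_value = 0),
      scales = c(max_value = "linear")
    )
    ch <- sample_population(pop, n, seed = cells$seed[i])
    if (stats::sd(ch$max_value) == 0) {
      warning("no between-individual variance in the true maximum at ",
              "max_sd = ", cells$max_sd[i], "; R-squared undefined")
      return(NA_real_)
    }
    ds <- simulate_dataset(ch, expr = expr, design = design, assay = assay,
                           n_events = 1, seed = cells$seed[i])
    summary(stats::lm(ds$observed$value ~ ch$max_value))$r.squared
  }, numeric(1))
  cells$n <- n
  cells[, c("peak_mean", "max_sd", "speed_sd", "r_squared", "n", "seed")]
}

#' Base population for the speed-scope covariation scenario
#'
#' The default population (mean time-to-maximum 30 min, log-normal
#' maximum) with the chosen correlation between time-to-maximum and
#' maximum imposed on the sampling scale. A negative correlation means
#' faster responders reach higher maxima.
#'
#' @param correlation correlation between `time_to_max` and `max_value`.
#' @return A [population_spec()].
#' @export
scenario_covariation_population <- function(correlation = 0) {
  set_correlation(default_population(), "time_to_max", "max_value",
                  correlation)
}

#' What does a single-timepoint measure reflect when speed and scope covary?
#'
#' For each combination of speed-scope correlation, between-individual
#' variation level, and replicate, simulates a population (mean peak time
#' 30 min), expresses one event per individual, and measures the curve
#' value at every timepoint in `times` under the standard small assay
#' error. At each timepoint two simple linear regressions are fit -
#' measured value on true speed (time-to-maximum) and on true maximum -
#' and both R-squared values are recorded.
#'
#' The assay error matters here: within-individual expression noise is
#' drawn from the population itself and therefore scales with the swept
#' between-individual SDs, so without a fixed noise floor even tiny true
#' differences would remain detectable and the low-variation cells would
#' look unrealistically measurable.
#'
#' @param correlations speed-scope correlations to sweep.
#' @param speed_sds named `c(low = , high = )` SDs of time-to-maximum (min).
#' @param max_sds named `c(low = , high = )` SDs of the maximum (ng/µl;
#'   sampled on the linear scale in this sweep so the SDs apply exactly).
#' @param times observation times to profile (min).
#' @param reps replicate simulations per cell.
#' @param n individuals per replicate.
#' @param fidelity expression fidelity.
#' @param error_sd assay noise SD (ng/µl).
#' @param seed master seed.
#' @return Long tibble: `correlation`, `speed_var`, `max_var`, `rep`,
#'   `time_min`, `trait` (`"speed"` or `"max"`), `r_squared`, `seed`.
#' @export
scenario_covariation <- function(correlations = c(-0.6, 0, 0.6),
                                 speed_sds = c(low = 2, high = 12),
                                 max_sds = c(low = 1, high = 10),
                                 times = 0:35, reps = 50, n = 100,
                                 fidelity = 0.8, error_sd = 1, seed = NULL) {
  stopifnot(all(abs(correlations) <= 1))
  seed <- resolve_seed(seed)
  cells <- tidyr::expand_grid(correlation = correlations,
                              speed_var = names(speed_sds),
                              max_var = names(max_sds),
                              rep = seq_len(reps))
  design <- sampling_design("fixed", fixed_times = times)
  expr <- expression_spec(fidelity)
  assay <- assay_model(error_sd)
  out <- vector("list", nrow(cells))
  for (i in seq_len(nrow(cells))) {
    s <- cell_seed(seed, i)
    pop <- population_spec(
      means = c(time_to_max = 30, max_value = 25),
      sds = c(time_to_max = speed_sds[[cells$speed_var[i]]],
              max_value = max_sds[[cells$max_var[i]]]),
      scales = c(max_value = "linear")
    )
    pop <- set_correlation(pop, "time_to_max", "max_value",
                           cells$correlation[i])
    ch <- sample_population(pop, n, seed = s)
    ds <- simulate_dataset(ch, expr = expr, design = design,
                           assay = assay, n_events = 1, seed = s)
    vals <- matrix(ds$observed$value, nrow = n, byrow = TRUE)
    r2 <- function(truth) apply(vals, 2, function(v) {
      summary(stats::lm(v ~ truth))$r.squared
    })
    out[[i]] <- tibble::tibble(
      correlation = cells$correlation[i], speed_var = cells$speed_var[i],
      max_var = cells$max_var[i], rep = cells$rep[i],
      time_min = rep(times, 2),
      trait = rep(c("speed", "max"), each = length(times)),
      r_squared = c(r2(ch$time_to_max), r2(ch$max_value)),
      seed = s
    )
  }
  dplyr::bind_rows(out)
}

#' Power to detect a true glucocorticoid-fitness relationship
#'
#' The true maximum explains a fixed share (default 80%) of fitness
#' variance. For each combination of between-individual variation in the
#' maximum (log-scale SD) and within-individual expression fidelity,
#' `reps` populations of `n` individuals are simulated and measured once
#' at `sample_time` with assay error; each replicate records the
#' correlation of fitness with the true maximum (sampling scale) and with
#' the observed value, and whether the simple regression of fitness on the
#' observed value is significant at the 5% level.
#'
#' @param between_sds named `c(low = , high = )` log-scale SDs of the
#'   maximum.
#' @param fidelities named `c(low = , high = )` expression fidelity where
#'   `low` means low *within*-individual variation (high fidelity).
#' @param n individuals per population.
#' @param reps simulated populations per cell.
#' @param max_share share of fitness variance from the true maximum.
#' @param sample_time observation time (min).
#' @param error_sd assay noise SD (ng/µl).
#' @param seed master seed.
#' @return Tibble: `between`, `within`, `rep`, `true_cor`, `obs_cor`,
#'   `p_value`, `detected`, `seed`.
#' @export
scenario_fitness_detection <- function(between_sds = c(low = 0.1, high = 0.5),
                                       fidelities = c(low = 0.9, high = 0.5),
                                       n = 50, reps = 50, max_share = 0.8,
                                       sample_time = 30, error_sd = 1,
                                       seed = NULL) {
  stopifnot(n >= 3)
  seed <- resolve_seed(seed)
  cells <- tidyr::expand_grid(between = names(between_sds),
                              within = names(fidelities),
                              rep = seq_len(reps))
  design <- sampling_design("fixed", fixed_times = sample_time)
  fspec <- fitness_spec(c(max_value = max_share),
                        unmeasured_share = 1 - max_share)
  assay <- assay_model(error_sd)
  out <- vector("list", nrow(cells))
  for (i in seq_len(nrow(cells))) {
    s <- cell_seed(seed, i)
    pop <- population_spec(sds = c(max_value = between_sds[[cells$between[i]]]))
    ch <- sample_population(pop, n, seed = s)
    ds <- simulate_dataset(ch, expr = expression_spec(fidelities[[cells$within[i]]]),
                           design = design, assay = assay, n_events = 1,
                           seed = s, fitness = fspec)
    true_max <- log(ch$max_value)  # sampling scale
    fit <- ds$fitness$fitness
    obs <- ds$observed$value
    p <- summary(stats::lm(fit ~ obs))$coefficients[2, 4]
    out[[i]] <- tibble::tibble(
      between = cells$between[i], within = cells$within[i],
      rep = cells$rep[i],
      true_cor = stats::cor(fit, true_max),
      obs_cor = stats::cor(fit, obs),
      p_value = p, detected = p < 0.05, seed = s
    )
  }
  dplyr::bind_rows(out)
}

#' Control and treatment populations for the sampling-scheme scenario
#'
#' The treatment group reaches its maximum on average 12 min (~40%) faster
#' than the control group (mean time-to-maximum 18 vs 30 min) with a
#' proportionally shorter onset delay, hence a steeper initial slope;
#' the distribution of the maximum itself is identical in both groups.
#'
#' @return Named list of two [population_spec()]s: `control`, `treatment`.
#' @export
scenario_sampling_populations <- function() {
  list(
    control = default_population(),
    treatment = population_spec(means = c(time_to_max = 18, onset_delay = 1.8),
                                sds = c(time_to_max = 3, onset_delay = 0.6))
  )
}

default_schemes <- function(n_samples = 3) {
  list(
    fixed_1_30_60 = sampling_design("fixed", fixed_times = c(1, 30, 60)),
    fixed_1_15_30 = sampling_design("fixed", fixed_times = c(1, 15, 30)),
    fixed_1_15_60 = sampling_design("fixed", fixed_times = c(1, 15, 60)),
    random = sampling_design("uniform_random", window = c(1, 60),
                             n_samples = n_samples),
    weighted = sampling_design("weighted_normal", center = 32, spread = 9,
                               n_samples = n_samples)
  )
}

#' Compare sampling schemes for detecting a group difference in speed
#'
#' Two groups differing in response speed (see
#' [scenario_sampling_populations()]) are each sampled once per individual
#' at `n_samples` times under each candidate scheme, directly from the
#' true response curves (no expression noise, no assay error). Per group
#' and scheme a penalized-spline smoother (a simple GAM of value on time)
#' is fit to the pooled points; the scheme is scored by (a) the mean
#' absolute error between the estimated and true group-mean curve over the
#' evaluation window and (b) the estimated group difference in the time of
#' the curve maximum.
#'
#' @param n_per_group individuals per group.
#' @param n_samples samples per individual.
#' @param schemes named list of [sampling_design()]s; default: the three
#'   standard fixed schemes (1/30/60, 1/15/30, 1/15/60), uniform-random
#'   over 1-60 min, and normal-weighted times (mean 32, SD 9 min).
#' @param reps paired replicates (the same simulated groups are observed
#'   under every scheme within a replicate).
#' @param eval_window `(min, max)` minutes over which curves are compared.
#' @param seed master seed.
#' @param keep_curves if `TRUE`, the fitted and true group curves of the
#'   first replicate are attached as attribute `"group_curves"`.
#' @return Tibble with one row per `(rep, scheme)`: `mae_control`,
#'   `mae_treatment`, `mae`, `est_peak_control`, `est_peak_treatment`,
#'   `est_peak_diff`, `true_peak_diff`, `n_obs`, `seed`.
#' @export
scenario_sampling_schemes <- function(n_per_group = 20, n_samples = 3,
                                      schemes = default_schemes(n_samples),
                                      reps = 1, eval_window = c(0, 60),
                                      seed = NULL, keep_curves = FALSE) {
  stopifnot(length(schemes) > 0, !is.null(names(schemes)))
  seed <- resolve_seed(seed)
  pops <- scenario_sampling_populations()
  expr <- expression_spec(1)          # sample the true curves directly
  noiseless <- assay_model(error_sd = 0)
  grid <- eval_window[1]:eval_window[2]
  fine <- seq(eval_window[1], eval_window[2], by = 0.25)
  out <- vector("list", reps * length(schemes))
  curves_out <- list()
  k <- 0
  for (r in seq_len(reps)) {
    cohorts <- lapply(seq_along(pops), function(g) {
      sample_population(pops[[g]], n_per_group,
                        seed = cell_seed(seed, r * 10 + g))
    })
    names(cohorts) <- names(pops)
    ## true group-mean curves
    true_mean <- lapply(cohorts, function(ch) {
      x <- cohort_matrix(ch)
      m <- sapply(seq_len(nrow(x)), function(j) {
        build_curve(row_params(x[j, ]))$values
      })
      rowMeans(m)[grid + 1]
    })
    true_peak <- vapply(true_mean, function(v) {
      grid[which.max(v)]
    }, numeric(1))
    true_peak_diff <- true_peak[["control"]] - true_peak[["treatment"]]
    for (sc in names(schemes)) {
      k <- k + 1
      s <- cell_seed(seed, r * 1000 + k)
      fits <- lapply(names(cohorts), function(g) {
        ds <- simulate_dataset(cohorts[[g]], expr = expr,
                               design = schemes[[sc]], assay = noiseless,
                               n_events = 1, seed = s + match(g, names(cohorts)))
        d <- ds$observed
        kk <- max(3, min(10, length(unique(round(d$time_min, 6)))))
        gm <- mgcv::gam(value ~ s(time_min, k = kk), data = d)
        ## never extrapolate the spline: outside the sampled time range the
        ## estimate is held at its boundary value, and the peak is searched
        ## within the sampled range only
        support <- range(d$time_min)
        clamp <- function(t) pmin(pmax(t, support[1]), support[2])
        pr <- stats::predict(gm, newdata = data.frame(time_min = clamp(grid)),
                             se.fit = TRUE)
        fine_in <- fine[fine >= support[1] & fine <= support[2]]
        prf <- stats::predict(gm, newdata = data.frame(time_min = fine_in))
        list(obs = d, est = as.numeric(pr$fit), se = as.numeric(pr$se.fit),
             peak = fine_in[which.max(prf)])
      })
      names(fits) <- names(cohorts)
      mae <- vapply(names(cohorts), function(g) {
        mean(abs(fits[[g]]$est - true_mean[[g]]))
      }, numeric(1))
      est_peak_diff <- fits$control$peak - fits$treatment$peak
      out[[k]] <- tibble::tibble(
        rep = r, scheme = sc,
        mae_control = mae[["control"]], mae_treatment = mae[["treatment"]],
        mae = mean(mae),
        est_peak_control = fits$control$peak,
        est_peak_treatment = fits$treatment$peak,
        est_peak_diff = est_peak_diff, true_peak_diff = true_peak_diff,
        n_obs = sum(vapply(fits, function(f) nrow(f$obs), numeric(1))),
        seed = s
      )
      if (keep_curves && r == 1) {
        curves_out[[sc]] <- dplyr::bind_rows(lapply(names(fits), function(g) {
          tibble::tibble(scheme = sc, group = g, time_min = grid,
                         estimate = fits[[g]]$est,
                         lower = fits[[g]]$est - 1.96 * fits[[g]]$se,
                         upper = fits[[g]]$est + 1.96 * fits[[g]]$se,
                         truth = true_mean[[g]])
        }))
      }
    }
  }
  res <- dplyr::bind_rows(out)
  if (keep_curves) attr(res, "group_curves") <- dplyr::bind_rows(curves_out)
  res
}
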