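#' Within-individual expression fidelity
#'
#' Each realized (expressed) response mixes the individual's true parameters
#' with a freshly drawn phenotype from the same population, on the sampling
#' scale. The fidelity weight `w` in \[0, 1\] controls how much of the
#' expressed value is determined by the true value (`w = 1`: perfect
#' repeatability; `w = 0`: every event is an independent draw). Because the
#' fresh draw comes from the full multivariate normal, the population
#' correlation structure is maintained among expressed parameters.
#'
#' Two mixing rules are available. `"convex"` takes
#' `w * true + (1 - w) * fresh`; it is the most literal reading of
#' "determined partly by the true value and partly by a new draw" but
#' shrinks the marginal variance of expressed values by `w^2 + (1 - w)^2`.
#' `"variance_preserving"` uses `mu + w * (true - mu) + sqrt(1 - w^2) *
#' (fresh - mu)`, which keeps the expressed marginal variance equal to the
#' population variance for every `w`.
#'
#' @param fidelity scalar or named per-parameter vector of weights in
#'   \[0, 1\]. Default 0.8 (moderate within-individual variation).
#' @param mode `"convex"` (default) or `"variance_preserving"`.
#' @return An `expression_spec` object.
#' @export
expression_spec <- function(fidelity = 0.8,
                            mode = c("convex", "variance_preserving")) {
  mode <- match.arg(mode)
  if (length(fidelity) == 1 && is.null(names(fidelity))) {
    fidelity <- stats::setNames(rep(as.numeric(fidelity), 7), PARAM_NAMES)
  } else {
    fidelity <- merge_named(stats::setNames(rep(0.8, 7), PARAM_NAMES),
                            fidelity, "fidelity")
  }
  if (any(!is.finite(fidelity)) || any(fidelity < 0 | fidelity > 1)) {
    stop("fidelity weights must lie in [0, 1]", call. = FALSE)
  }
  structure(list(fidelity = fidelity[PARAM_NAMES], mode = mode),
            class = "expression_spec")
}

#' Sampling-time designs
#'
#' How measurement times are allocated to individuals within one sampling
#' event: the same fixed times for everyone (standard standardized
#' protocols), independent uniform draws over a window, or draws from a
#' normal distribution centred where maximum levels are expected
#' (truncated to \[0, t_end\] by redraw).
#'
#' @param kind `"fixed"`, `"uniform_random"` or `"weighted_normal"`.
#' @param fixed_times minutes, for `kind = "fixed"`.
#' @param window length-2 `(min, max)` minutes, for `kind = "uniform_random"`.
#' @param center,spread minutes, for `kind = "weighted_normal"`.
#' @param n_samples samples per event (ignored for `"fixed"`, which uses
#'   `length(fixed_times)`).
#' @return A `sampling_design` object.
#' @examples
#' sampling_design("fixed", fixed_times = c(1, 15, 30))
#' sampling_design("weighted_normal", center = 32, spread = 9, n_samples = 3)
#' @export
sampling_design <- function(kind = c("fixed", "uniform_random", "weighted_normal"),
                            fixed_times = c(1, 15, 30), window = c(1, 60),
                            center = 32, spread = 9, n_samples = 3) {
  kind <- match.arg(kind)
  if (kind == "fixed") {
    if (length(fixed_times) < 1 || any(!is.finite(fixed_times)) ||
        any(fixed_times < 0)) {
      stop("fixed_times must be non-negative minutes", call. = FALSE)
    }
    n_samples <- length(fixed_times)
  }
  if (kind == "uniform_random") {
    if (length(window) != 2 || diff(window) <= 0) {
      stop("window must be (min, max) with max > min", call. = FALSE)
    }
  }
  if (kind == "weighted_normal" && (!is.finite(spread) || spread <= 0)) {
    stop("spread must be > 0", call. = FALSE)
  }
  if (n_samples < 1) stop("n_samples must be >= 1", call. = FALSE)
  structure(list(kind = kind, fixed_times = sort(fixed_times),
                 window = window, center = center, spread = spread,
                 n_samples = n_samples),
            class = "sampling_design")
}

#' Assay (measurement) error model
#'
#' Additive Gaussian noise on the concentration scale, clamped at `floor`
#' (concentrations cannot be negative).
#'
#' @param error_sd noise SD in ng/µl, >= 0. Default 1 (a small amount of
#'   assay error).
#' @param floor lower clamp, default 0.
#' @return An `assay_model` object.
#' @export
assay_model <- function(error_sd = 1, floor = 0) {
  if (!is.finite(error_sd) || error_sd < 0) stop("error_sd must be >= 0")
  structure(list(error_sd = error_sd, floor = floor), class = "assay_model")
}

#' Express one response event from a true phenotype
#'
#' Mixes the true parameters with a fresh population draw per
#' [expression_spec()]; log-scale parameters are mixed on the log scale and
#' exponentiated. If the mixed parameters violate the curve invariants the
#' fresh draw is rejection-resampled.
#'
#' @param true_params a [response_params()] object (the individual's truth).
#' @param expr an [expression_spec()].
#' @param pop the [population_spec()] the individual was drawn from.
#' @return A [response_params()] object for the expressed event.
#' @export
express_event <- function(true_params, expr, pop) {
  stopifnot(inherits(true_params, "response_params"))
  tm <- matrix(unlist(true_params)[PARAM_NAMES], nrow = 1,
               dimnames = list(NULL, PARAM_NAMES))
  out <- express_matrix(to_sampling_scale(tm, pop), expr, pop)
  row_params(out[1, ])
}

## Vectorised expression: `true_s` is an m x 7 matrix on the SAMPLING scale
## (one row per event to express; repeat rows for repeated events).
## Returns an m x 7 matrix on the natural scale.
express_matrix <- function(true_s, expr, pop, max_rounds = 1000) {
  m <- nrow(true_s)
  w <- expr$fidelity
  mix <- function(true_rows, fresh_nat) {
    f <- to_sampling_scale(fresh_nat, pop)
    e <- if (expr$mode == "convex") {
      sweep(true_rows, 2, w, "*") + sweep(f, 2, 1 - w, "*")
    } else {
      mu <- pop$means
      sweep(sweep(true_rows, 2, mu, "-"), 2, w, "*") +
        sweep(sweep(f, 2, mu, "-"), 2, sqrt(1 - w^2), "*") +
        matrix(mu, nrow(true_rows), 7, byrow = TRUE)
    }
    from_sampling_scale(e, pop)
  }
  out <- mix(true_s, sample_raw(pop, m))
  ok <- validate_params(out)
  rounds <- 0
  while (any(!ok)) {
    rounds <- rounds + 1
    if (rounds > max_rounds) {
      stop("could not express valid parameters after ", max_rounds,
           " resampling rounds", call. = FALSE)
    }
    idx <- which(!ok)
    out[idx, ] <- mix(true_s[idx, , drop = FALSE],
                      sample_raw(pop, length(idx)))
    ok[idx] <- validate_params(out[idx, , drop = FALSE])
  }
  out
}

#' Generate per-individual sampling times
#'
#' @param design a [sampling_design()].
#' @param n_individuals number of individuals.
#' @param t_end upper bound of valid times (min).
#' @param seed optional integer seed.
#' @return A list of `n_individuals` sorted numeric time vectors.
#' @export
sample_times <- function(design, n_individuals, t_end = 120, seed = NULL) {
  stopifnot(inherits(design, "sampling_design"), n_individuals >= 1)
  if (!is.null(seed)) set.seed(seed)
  k <- design$n_samples
  switch(design$kind,
    fixed = {
      if (any(design$fixed_times > t_end)) {
        stop("fixed_times exceed t_end = ", t_end, call. = FALSE)
      }
      replicate(n_individuals, design$fixed_times, simplify = FALSE)
    },
    uniform_random = {
      w <- pmin(pmax(design$window, 0), t_end)
      if (diff(w) <= 0) stop("empty sampling window", call. = FALSE)
      lapply(seq_len(n_individuals),
             function(i) sort(stats::runif(k, w[1], w[2])))
    },
    weighted_normal = {
      lapply(seq_len(n_individuals), function(i) {
        t <- stats::rnorm(k, design$center, design$spread)
        while (any(t < 0 | t > t_end)) {
          bad <- t < 0 | t > t_end
          t[bad] <- stats::rnorm(sum(bad), design$center, design$spread)
        }
        sort(t)
      })
    }
  )
}

#' Measure a response curve at given times
#'
#' Values are read off the smoothed 1-minute curve (linear interpolation
#' for non-integer times), with additive Gaussian assay noise clamped at
#' the assay floor.
#'
#' @param curve a `response_curve` from [build_curve()].
#' @param times sampling times within the curve grid.
#' @param assay an [assay_model()].
#' @return Measured concentrations at `times`.
#' @export
observe <- function(curve, times, assay = assay_model()) {
  stopifnot(inherits(assay, "assay_model"))
  v <- curve_value(curve, times)
  if (assay$error_sd > 0) {
    v <- v + stats::rnorm(length(v), 0, assay$error_sd)
  }
  pmax(v, assay$floor)
}
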