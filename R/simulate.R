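## Deterministic per-stage child seeds: changing, say, the sampling design
## must not perturb the cohort. Kept below 2^31 - 1.
STAGE_OFFSETS <- c(population = 1L, expression = 2L, times = 3L,
                   assay = 4L, fitness = 5L)

child_seed <- function(seed, stage) {
  off <- STAGE_OFFSETS[[stage]]
  as.integer(((as.numeric(seed) + 1) * 2654435 + off * 40503) %% 2147483647)
}

#' Simulate an observed repeated-measures hormone dataset
#'
#' The full observation pipeline: each individual in the cohort expresses
#' `n_events` responses (true parameters mixed with fresh population draws
#' per the expression fidelity), each expressed response is realized as a
#' smoothed minute-resolution curve, and each curve is measured at the
#' design's sampling times with assay error. All randomness flows from
#' `seed` through independent per-stage child streams, so e.g. changing
#' the assay model does not change the expressed curves.
#'
#' @param cohort a `cohort` from [sample_population()].
#' @param expr an [expression_spec()].
#' @param design a [sampling_design()]; times are drawn once per individual
#'   and shared across that individual's events.
#' @param assay an [assay_model()].
#' @param n_events repeated sampling events per individual (>= 1).
#' @param seed optional integer master seed.
#' @param t_end,smooth_span curve construction settings, see [build_curve()].
#' @param fitness optional [fitness_spec()]; if supplied, per-individual
#'   fitness is generated from the true parameters.
#' @return An `observed_dataset`: list with
#'   * `observed`: tibble `(individual_id, event_id, time_min, value)`,
#'   * `truth_individuals`: the cohort (true parameters),
#'   * `truth_events`: tibble of expressed parameters per event,
#'   * `curves`: matrix of smoothed event curves (one row per event),
#'   * `grid`: the curve time grid,
#'   * `fitness`: tibble `(individual_id, fitness)` or `NULL`,
#'   plus the specs used.
#' @examples
#' ch <- sample_population(default_population(), 4, seed = 1)
#' ds <- simulate_dataset(ch, design = sampling_design("fixed"),
#'                        n_events = 2, seed = 1)
#' ds$observed
#' @export
simulate_dataset <- function(cohort, expr = expression_spec(),
                             design = sampling_design("fixed"),
                             assay = assay_model(), n_events = 1,
                             seed = NULL, t_end = 120, smooth_span = 0.3,
                             fitness = NULL) {
  stopifnot(inherits(cohort, "cohort"), inherits(expr, "expression_spec"),
            inherits(design, "sampling_design"))
  if (n_events < 1) stop("n_events must be >= 1")
  pop <- cohort_spec(cohort)
  n <- nrow(cohort)

  ## expression stage
  if (!is.null(seed)) set.seed(child_seed(seed, "expression"))
  true_s <- cohort_matrix(cohort, "sampling", pop)
  key <- tidyr::expand_grid(individual_id = cohort$individual_id,
                            event_id = seq_len(n_events))
  expressed <- express_matrix(true_s[rep(seq_len(n), each = n_events), ,
                                     drop = FALSE], expr, pop)
  truth_events <- dplyr::bind_cols(key, tibble::as_tibble(as.data.frame(expressed)))

  ## sampling-time stage
  times_list <- sample_times(design, n, t_end = t_end,
                             seed = if (!is.null(seed)) child_seed(seed, "times"))

  ## curve realization (deterministic given expressed parameters)
  grid <- 0:floor(t_end)
  curves <- matrix(NA_real_, nrow(expressed), length(grid))
  clean <- vector("list", nrow(expressed))
  for (r in seq_len(nrow(expressed))) {
    cv <- build_curve(row_params(expressed[r, ]), t_end = t_end,
                      smooth_span = smooth_span)
    curves[r, ] <- cv$values
    clean[[r]] <- curve_value(cv, times_list[[match(key$individual_id[r],
                                                    cohort$individual_id)]])
  }

  ## assay stage
  if (!is.null(seed)) set.seed(child_seed(seed, "assay"))
  observed <- dplyr::bind_cols(
    key[rep(seq_len(nrow(key)), lengths(clean)), ],
    tibble::tibble(
      time_min = unlist(lapply(seq_len(nrow(key)), function(r) {
        times_list[[match(key$individual_id[r], cohort$individual_id)]]
      })),
      value = unlist(clean)
    )
  )
  if (assay$error_sd > 0) {
    observed$value <- observed$value +
      stats::rnorm(nrow(observed), 0, assay$error_sd)
  }
  observed$value <- pmax(observed$value, assay$floor)

  ## fitness stage
  fit <- NULL
  if (!is.null(fitness)) {
    fit <- assign_fitness(cohort, fitness,
                          seed = if (!is.null(seed)) child_seed(seed, "fitness"))
  }

  structure(list(observed = observed, truth_individuals = cohort,
                 truth_events = truth_events, curves = curves,
                 curve_key = key, grid = grid, fitness = fit,
                 population = pop, expression = expr, design = design,
                 assay = assay, seed = seed, t_end = t_end,
                 smooth_span = smooth_span),
            class = "observed_dataset")
}

#' Fitness variance shares
#'
#' Specifies how much of the variance in a single fitness measure is
#' attributable to each true curve parameter, with the remainder
#' (`unmeasured_share`) coming from unmeasured traits. Shares must sum
#' to 1.
#'
#' @param variance_share named numeric of per-parameter shares in \[0, 1\]
#'   (unnamed parameters get 0).
#' @param unmeasured_share share for unmeasured traits.
#' @return A `fitness_spec` object.
#' @examples
#' fitness_spec(c(max_value = 0.8), unmeasured_share = 0.2)
#' @export
fitness_spec <- function(variance_share, unmeasured_share) {
  v <- merge_named(stats::setNames(rep(0, 7), PARAM_NAMES),
                   variance_share, "variance_share")
  if (any(v < 0 | v > 1) || unmeasured_share < 0 || unmeasured_share > 1) {
    stop("variance shares must lie in [0, 1]", call. = FALSE)
  }
  if (abs(sum(v) + unmeasured_share - 1) > 1e-9) {
    stop("variance shares plus unmeasured_share must sum to 1 (got ",
         signif(sum(v) + unmeasured_share, 6), ")", call. = FALSE)
  }
  structure(list(variance_share = v, unmeasured_share = unmeasured_share),
            class = "fitness_spec")
}

#' Generate fitness from true phenotypes
#'
#' Fitness for individual *j* is `sum_i sqrt(v_i) * z_ij + sqrt(v_u) * e_j`
#' where `z_ij` is the cohort z-score of parameter *i* on its sampling
#' scale and `e_j` is standard normal. With uncorrelated parameters the
#' R-squared of a regression of fitness on true parameter *i* is therefore
#' approximately the configured share `v_i`.
#'
#' @param cohort a `cohort` from [sample_population()].
#' @param spec a [fitness_spec()].
#' @param seed optional integer seed.
#' @return Tibble `(individual_id, fitness)`.
#' @export
assign_fitness <- function(cohort, spec, seed = NULL) {
  stopifnot(inherits(cohort, "cohort"), inherits(spec, "fitness_spec"))
  if (!is.null(seed)) set.seed(seed)
  x <- cohort_matrix(cohort, "sampling")
  v <- spec$variance_share
  sds <- apply(x, 2, stats::sd)
  if (any(v > 0 & (is.na(sds) | sds == 0))) {
    stop("cannot z-score a parameter with zero variance but nonzero ",
         "fitness share", call. = FALSE)
  }
  z <- scale(x)
  z[, is.na(sds) | sds == 0] <- 0
  f <- as.numeric(z %*% sqrt(v)) +
    sqrt(spec$unmeasured_share) * stats::rnorm(nrow(x))
  tibble::tibble(individual_id = cohort$individual_id, fitness = f)
}

#' @export
print.observed_dataset <- function(x, ...) {
  cat("<observed_dataset> ", nrow(x$truth_individuals), " individuals x ",
      max(x$curve_key$event_id), " events, ", nrow(x$observed),
      " measurements\n", sep = "")
  print(utils::head(x$observed, 5))
  invisible(x)
}
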