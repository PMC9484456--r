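#' Assemble a full simulation run configuration
#'
#' Bundles every knob of the observation pipeline with documented
#' defaults. This is the object the YAML/JSON config files round-trip
#' through.
#'
#' @param population a [population_spec()].
#' @param expression an [expression_spec()].
#' @param design a [sampling_design()].
#' @param assay an [assay_model()].
#' @param fitness optional [fitness_spec()].
#' @param n_individuals,n_events cohort size and events per individual.
#' @param t_end,smooth_span curve settings, see [build_curve()].
#' @param seed optional master seed.
#' @param out_dir optional output directory for [write_dataset()].
#' @return A `run_config` object.
#' @export
run_config <- function(population = default_population(),
                       expression = expression_spec(),
                       design = sampling_design("fixed"),
                       assay = assay_model(), fitness = NULL,
                       n_individuals = 20, n_events = 1,
                       t_end = 120, smooth_span = 0.3, seed = NULL,
                       out_dir = NULL) {
  stopifnot(inherits(population, "population_spec"),
            inherits(expression, "expression_spec"),
            inherits(design, "sampling_design"),
            inherits(assay, "assay_model"),
            is.null(fitness) || inherits(fitness, "fitness_spec"),
            n_individuals >= 1, n_events >= 1)
  structure(list(population = population, expression = expression,
                 design = design, assay = assay, fitness = fitness,
                 n_individuals = as.integer(n_individuals),
                 n_events = as.integer(n_events), t_end = t_end,
                 smooth_span = smooth_span,
                 seed = if (!is.null(seed)) as.integer(seed),
                 out_dir = out_dir),
            class = "run_config")
}

CONFIG_KEYS <- list(
  top = c("population", "expression", "design", "assay", "fitness",
          "n_individuals", "n_events", "t_end", "smooth_span", "seed",
          "out_dir"),
  population = c("means", "sds", "scales", "correlation"),
  expression = c("fidelity", "mode"),
  design = c("kind", "fixed_times", "window", "center", "spread",
             "n_samples"),
  assay = c("error_sd", "floor"),
  fitness = c("variance_share", "unmeasured_share")
)

check_keys <- function(block, where) {
  unknown <- setdiff(names(block), CONFIG_KEYS[[where]])
  if (length(unknown) > 0) {
    stop("unknown config key", if (length(unknown) > 1) "s", " at `",
         if (where == "top") "" else paste0(where, "."),
         paste(unknown, collapse = "`, `"), "`", call. = FALSE)
  }
  invisible(block)
}

#' Load a run configuration from YAML or JSON
#'
#' Missing blocks fall back to the documented defaults; unknown keys are
#' rejected with the offending path. The correlation block accepts either
#' a full 7x7 matrix (list of rows, ordered as the parameter names) or a
#' list of `{param1, param2, rho}` entries for the non-zero off-diagonals.
#'
#' @param path path to a `.yaml`/`.yml` or `.json` file. An empty file
#'   yields the all-defaults configuration.
#' @return A [run_config()].
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (is.null(raw)) raw <- list()
  check_keys(raw, "top")
  pop <- if (is.null(raw$population)) default_population() else {
    b <- check_keys(raw$population, "population")
    population_spec(means = unlist(b$means), sds = unlist(b$sds),
                    scales = unlist(b$scales),
                    correlation = parse_correlation(b$correlation))
  }
  expr <- if (is.null(raw$expression)) expression_spec() else {
    b <- check_keys(raw$expression, "expression")
    do.call(expression_spec, c(
      if (!is.null(b$fidelity)) list(fidelity = unlist(b$fidelity)),
      if (!is.null(b$mode)) list(mode = b$mode)))
  }
  design <- if (is.null(raw$design)) sampling_design("fixed") else {
    b <- check_keys(raw$design, "design")
    do.call(sampling_design, lapply(b, unlist))
  }
  assay <- if (is.null(raw$assay)) assay_model() else {
    b <- check_keys(raw$assay, "assay")
    do.call(assay_model, b)
  }
  fitness <- if (is.null(raw$fitness)) NULL else {
    b <- check_keys(raw$fitness, "fitness")
    fitness_spec(unlist(b$variance_share), b$unmeasured_share)
  }
  run_config(population = pop, expression = expr, design = design,
             assay = assay, fitness = fitness,
             n_individuals = raw$n_individuals %||% 20,
             n_events = raw$n_events %||% 1,
             t_end = raw$t_end %||% 120,
             smooth_span = raw$smooth_span %||% 0.3,
             seed = raw$seed, out_dir = raw$out_dir)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

parse_correlation <- function(x) {
  if (is.null(x)) return(NULL)
  if (is.matrix(x)) return(x)
  if (is.list(x) && all(vapply(x, function(e)
      all(c("param1", "param2", "rho") %in% names(e)), logical(1)))) {
    r <- diag_correlation()
    for (e in x) {
      r[e$param1, e$param2] <- e$rho
      r[e$param2, e$param1] <- e$rho
    }
    return(r)
  }
  m <- do.call(rbind, lapply(x, unlist))
  if (!all(dim(m) == c(7, 7))) {
    stop("correlation must be a 7x7 matrix or a list of ",
         "{param1, param2, rho} entries", call. = FALSE)
  }
  dimnames(m) <- list(PARAM_NAMES, PARAM_NAMES)
  m
}

#' Save a run configuration as canonical YAML
#'
#' @param config a [run_config()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
save_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  yaml::write_yaml(as_config_list(config), path, precision = 15)
  invisible(path)
}

as_config_list <- function(config) {
  pop <- config$population
  out <- list(
    population = list(
      means = as.list(pop$means), sds = as.list(pop$sds),
      scales = as.list(pop$scales),
      correlation = lapply(seq_len(7), function(i) as.numeric(pop$correlation[i, ]))
    ),
    expression = list(fidelity = as.list(config$expression$fidelity),
                      mode = config$expression$mode),
    design = list(kind = config$design$kind,
                  fixed_times = config$design$fixed_times,
                  window = config$design$window,
                  center = config$design$center,
                  spread = config$design$spread,
                  n_samples = config$design$n_samples),
    assay = list(error_sd = config$assay$error_sd,
                 floor = config$assay$floor),
    n_individuals = config$n_individuals, n_events = config$n_events,
    t_end = config$t_end, smooth_span = config$smooth_span
  )
  if (!is.null(config$fitness)) {
    out$fitness <- list(
      variance_share = as.list(config$fitness$variance_share),
      unmeasured_share = config$fitness$unmeasured_share)
  }
  if (!is.null(config$seed)) out$seed <- config$seed
  if (!is.null(config$out_dir)) out$out_dir <- config$out_dir
  out
}

#' Run the full simulation described by a configuration
#'
#' Samples the cohort and simulates the observed dataset (and fitness, if
#' configured), all from the configuration's master seed.
#'
#' @param config a [run_config()].
#' @param seed optional override of the config's seed.
#' @return An `observed_dataset`.
#' @export
run_simulation <- function(config, seed = NULL) {
  stopifnot(inherits(config, "run_config"))
  seed <- seed %||% config$seed
  cohort <- sample_population(config$population, config$n_individuals,
                              seed = if (!is.null(seed))
                                child_seed(seed, "population"))
  simulate_dataset(cohort, expr = config$expression, design = config$design,
                   assay = config$assay, n_events = config$n_events,
                   seed = seed, t_end = config$t_end,
                   smooth_span = config$smooth_span,
                   fitness = config$fitness)
}

#' Write a simulated dataset as tidy CSV files
#'
#' Writes `observed.csv` (`individual_id,event_id,time_min,value`),
#' `truth_individuals.csv` (true parameters per individual),
#' `truth_events.csv` (expressed parameters per event) and, when fitness
#' was generated, `fitness.csv`. Files are UTF-8, '.'-decimal,
#' newline-terminated, and byte-stable for identical input.
#'
#' @param dataset an `observed_dataset`.
#' @param dir output directory (created if needed).
#' @return Named character vector of file paths, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "observed_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(observed = file.path(dir, "observed.csv"),
             truth_individuals = file.path(dir, "truth_individuals.csv"),
             truth_events = file.path(dir, "truth_events.csv"))
  readr::write_csv(dataset$observed[, c("individual_id", "event_id",
                                        "time_min", "value")],
                   paths[["observed"]])
  readr::write_csv(tibble::as_tibble(as.data.frame(
    dataset$truth_individuals)), paths[["truth_individuals"]])
  readr::write_csv(dataset$truth_events, paths[["truth_events"]])
  if (!is.null(dataset$fitness)) {
    paths <- c(paths, fitness = file.path(dir, "fitness.csv"))
    readr::write_csv(dataset$fitness, paths[["fitness"]])
  }
  invisible(paths)
}

#' Read a long-format hormone dataset from CSV
#'
#' For analyzing field data with the repeatability functions: any CSV with
#' columns `individual_id`, `event_id`, `time_min`, `value`.
#'
#' @param path CSV path.
#' @return A tibble in the long observed format.
#' @export
read_observed <- function(path) {
  obs <- readr::read_csv(path, show_col_types = FALSE)
  check_long_format(obs)
  obs
}
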