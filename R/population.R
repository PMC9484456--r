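#' Specify a population distribution over curve parameters
#'
#' Individual phenotypes are drawn from a 7-dimensional multivariate normal
#' on the *sampling scale*: parameters flagged `scale = "log"` have their
#' mean and SD interpreted on the natural-log scale and are exponentiated
#' after the joint draw, which yields a right-skewed marginal (typical of
#' maximum glucocorticoid levels) while the correlation structure is
#' specified on the sampling scale.
#'
#' Arguments are merged over the package default population, so only the
#' entries being changed need to be supplied.
#'
#' @param means named numeric; per-parameter means (log-units where
#'   `scale = "log"`). Names from
#'   `c("baseline","onset_delay","time_to_max","max_value",
#'   "plateau_duration","return_duration","end_value")`.
#' @param sds named numeric; per-parameter SDs on the same scale, >= 0.
#' @param scales named character; `"linear"` or `"log"` per parameter.
#' @param correlation 7x7 symmetric correlation matrix (unit diagonal,
#'   entries in \[-1, 1\], positive semidefinite up to a small repair
#'   tolerance). Rows/columns may be named with the parameter names.
#' @return A `population_spec` object.
#' @examples
#' spec <- population_spec(sds = c(time_to_max = 12))
#' spec
#' @export
population_spec <- function(means = NULL, sds = NULL, scales = NULL,
                            correlation = NULL) {
  d <- default_population_values()
  d$means <- merge_named(d$means, means, "means")
  d$sds <- merge_named(d$sds, sds, "sds")
  d$scales <- merge_named(d$scales, scales, "scales")
  if (!is.null(correlation)) d$correlation <- correlation
  spec <- structure(d, class = "population_spec")
  validate_population_spec(spec)
}

## Package default population: chosen so that simulated cohorts visually
## resemble published acute corticosterone responses (baseline ~5 ng/ul,
## log-normal maximum around 25 ng/ul, peak near 30 min).
default_population_values <- function() {
  list(
    means = c(baseline = 5, onset_delay = 3, time_to_max = 30,
              max_value = log(25), plateau_duration = 10,
              return_duration = 30, end_value = 6),
    sds = c(baseline = 1, onset_delay = 1, time_to_max = 5,
            max_value = 0.3, plateau_duration = 3,
            return_duration = 5, end_value = 1),
    scales = c(baseline = "linear", onset_delay = "linear",
               time_to_max = "linear", max_value = "log",
               plateau_duration = "linear", return_duration = "linear",
               end_value = "linear"),
    correlation = diag_correlation()
  )
}

#' Default population specification
#'
#' @return The package default [population_spec()] (log-normal maximum with
#'   median 25 ng/µl, mean peak time 30 min, uncorrelated parameters).
#' @export
default_population <- function() population_spec()

diag_correlation <- function() {
  r <- diag(7)
  dimnames(r) <- list(PARAM_NAMES, PARAM_NAMES)
  r
}

merge_named <- function(base, override, what) {
  if (is.null(override)) return(base)
  if (is.null(names(override)) || !all(names(override) %in% PARAM_NAMES)) {
    stop("`", what, "` must be named with response parameter names",
         call. = FALSE)
  }
  base[names(override)] <- override
  base
}

#' Set one correlation entry of a population specification
#'
#' @param spec a [population_spec()].
#' @param param1,param2 parameter names.
#' @param rho correlation in \[-1, 1\] on the sampling scale.
#' @return The modified `population_spec`.
#' @export
set_correlation <- function(spec, param1, param2, rho) {
  stopifnot(inherits(spec, "population_spec"),
            param1 %in% PARAM_NAMES, param2 %in% PARAM_NAMES,
            param1 != param2)
  spec$correlation[param1, param2] <- rho
  spec$correlation[param2, param1] <- rho
  validate_population_spec(spec)
}

validate_population_spec <- function(spec) {
  for (field in c("means", "sds", "scales")) {
    v <- spec[[field]]
    if (length(v) != 7 || !setequal(names(v), PARAM_NAMES)) {
      stop("`", field, "` must cover all seven parameters", call. = FALSE)
    }
    spec[[field]] <- v[PARAM_NAMES]
  }
  if (any(!is.finite(spec$means))) stop("non-finite mean", call. = FALSE)
  if (any(!is.finite(spec$sds)) || any(spec$sds < 0)) {
    stop("sds must be finite and >= 0", call. = FALSE)
  }
  if (!all(spec$scales %in% c("linear", "log"))) {
    stop("scales must be 'linear' or 'log'", call. = FALSE)
  }
  r <- as.matrix(spec$correlation)
  if (!all(dim(r) == c(7, 7))) stop("correlation must be 7x7", call. = FALSE)
  if (is.null(dimnames(r))) dimnames(r) <- list(PARAM_NAMES, PARAM_NAMES)
  r <- r[PARAM_NAMES, PARAM_NAMES]
  if (max(abs(r - t(r))) > 1e-8) stop("correlation must be symmetric", call. = FALSE)
  if (any(abs(diag(r) - 1) > 1e-8)) stop("correlation diagonal must be 1", call. = FALSE)
  bad <- which(abs(r) > 1 + 1e-12, arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf("correlation[%s,%s] = %.3g outside [-1, 1]",
                 PARAM_NAMES[bad[1, 1]], PARAM_NAMES[bad[1, 2]],
                 r[bad[1, , drop = FALSE]]), call. = FALSE)
  }
  r <- repair_psd(r)
  zero_sd <- spec$sds == 0
  off <- r - diag(diag(r))
  if (any(zero_sd) && any(abs(off[zero_sd, ]) > 1e-8)) {
    stop("parameters with sd = 0 must have zero off-diagonal correlations",
         call. = FALSE)
  }
  spec$correlation <- r
  spec
}

## Clip tiny negative eigenvalues (rounding in user configs); reject
## genuinely indefinite matrices.
repair_psd <- function(r, tol = 1e-8) {
  e <- eigen(r, symmetric = TRUE)
  if (min(e$values) >= 0) return(r)
  if (min(e$values) < -tol) {
    stop("correlation matrix is not positive semidefinite (min eigenvalue ",
         signif(min(e$values), 3), ")", call. = FALSE)
  }
  v <- pmax(e$values, 0)
  m <- e$vectors %*% (v * t(e$vectors))
  d <- sqrt(diag(m))
  m <- m / tcrossprod(d)
  dimnames(m) <- dimnames(r)
  (m + t(m)) / 2
}

## Draw n VALID phenotypes (natural scale) from the spec using the current
## RNG state. Invalid draws (negative durations, onset >= peak, max below
## baseline, ...) are rejection-resampled so the joint shape is preserved.
sample_raw <- function(spec, n, max_rounds = 1000) {
  sigma <- diag(spec$sds) %*% spec$correlation %*% diag(spec$sds)
  draw <- function(m) {
    x <- MASS::mvrnorm(m, mu = spec$means, Sigma = sigma)
    x <- matrix(x, ncol = 7, dimnames = list(NULL, PARAM_NAMES))
    from_sampling_scale(x, spec)
  }
  x <- draw(n)
  ok <- validate_params(x)
  if (n >= 20 && mean(ok) < 0.5) {
    stop("more than 50% of draws violate the response-parameter ",
         "invariants; re-specify the population (acceptance rate ",
         signif(mean(ok), 2), ")", call. = FALSE)
  }
  rounds <- 0
  while (any(!ok)) {
    rounds <- rounds + 1
    if (rounds > max_rounds) {
      stop("could not draw valid parameters after ", max_rounds,
           " resampling rounds", call. = FALSE)
    }
    idx <- which(!ok)
    x[idx, ] <- draw(length(idx))
    ok[idx] <- validate_params(x[idx, , drop = FALSE])
  }
  x
}

to_sampling_scale <- function(x, spec) {
  lg <- names(spec$scales)[spec$scales == "log"]
  x[, lg] <- log(x[, lg, drop = FALSE])
  x
}

from_sampling_scale <- function(x, spec) {
  lg <- names(spec$scales)[spec$scales == "log"]
  x[, lg] <- exp(x[, lg, drop = FALSE])
  x
}

#' Sample a cohort of true phenotypes
#'
#' Draws `n` individuals from the population's multivariate normal on the
#' sampling scale (log-scale parameters exponentiated after the joint
#' draw). Draws violating the curve-parameter invariants are rejected and
#' resampled per individual, so re-specify the population if the rejection
#' rate exceeds 50%.
#'
#' @param spec a [population_spec()].
#' @param n number of individuals (>= 1).
#' @param seed optional integer; makes the cohort reproducible.
#' @return A `cohort`: tibble with `individual_id` and one column per
#'   parameter (natural scale), carrying the generating spec and seed as
#'   attributes.
#' @examples
#' ch <- sample_population(default_population(), 5, seed = 1)
#' ch
#' @export
sample_population <- function(spec, n, seed = NULL) {
  stopifnot(inherits(spec, "population_spec"), n >= 1)
  if (!is.null(seed)) set.seed(seed)
  x <- sample_raw(spec, n)
  ch <- tibble::as_tibble(as.data.frame(x))
  ch <- tibble::add_column(ch, individual_id = seq_len(n), .before = 1)
  attr(ch, "population_spec") <- spec
  attr(ch, "seed") <- seed
  class(ch) <- c("cohort", class(ch))
  ch
}

cohort_spec <- function(cohort) {
  spec <- attr(cohort, "population_spec")
  if (is.null(spec)) {
    stop("this cohort does not carry its population_spec attribute ",
         "(was it subset or rebuilt?)", call. = FALSE)
  }
  spec
}

## cohort -> n x 7 matrix of true parameters on the given scale
cohort_matrix <- function(cohort, scale = c("natural", "sampling"),
                          spec = cohort_spec(cohort)) {
  scale <- match.arg(scale)
  x <- as.matrix(as.data.frame(cohort)[, PARAM_NAMES])
  if (scale == "sampling") x <- to_sampling_scale(x, spec)
  x
}

## one cohort row -> response_params
row_params <- function(x) {
  do.call(response_params, as.list(x[PARAM_NAMES]))
}

#' @export
print.population_spec <- function(x, ...) {
  cat("<population_spec>\n")
  df <- data.frame(mean = x$means, sd = x$sds, scale = x$scales)
  print(df)
  off <- x$correlation - diag(7)
  if (any(abs(off) > 0)) {
    cat("non-zero correlations:\n")
    idx <- which(abs(off) > 0 & upper.tri(off), arr.ind = TRUE)
    for (k in seq_len(nrow(idx))) {
      cat("  ", PARAM_NAMES[idx[k, 1]], "~", PARAM_NAMES[idx[k, 2]], "=",
          x$correlation[idx[k, 1], idx[k, 2]], "\n")
    }
  } else cat("correlations: identity\n")
  invisible(x)
}
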