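#' Build a smoothed minute-resolution response curve
#'
#' The five turning points are linearly interpolated onto an integer-minute
#' grid from 0 to `t_end` (values past the final turning point are held at
#' the recovery level), then smoothed by locally weighted linear regression
#' on the grid. Smoothed concentrations are clamped at zero from below.
#'
#' @param params a [response_params()] object.
#' @param t_end last minute of the grid; should be at least
#'   `time_to_max + plateau_duration + return_duration` or the curve is
#'   truncated.
#' @param smooth_span smoothing bandwidth as a fraction of the 120-minute
#'   reference window, in (0, 1]; each local fit uses about
#'   `smooth_span * 120` minutes of curve, so lengthening `t_end` does not
#'   change the curve away from the old boundary. The default 0.3 gives
#'   curves with rounded shoulders similar to empirical responses.
#' @return A `response_curve`: list with `times` (integer minutes 0..t_end),
#'   `values` (ng/µl, same length) and `params`.
#' @examples
#' p <- response_params(5, 3, 30, 25, 10, 20, 6)
#' cv <- build_curve(p)
#' max(cv$values)
#' @export
build_curve <- function(params, t_end = 120, smooth_span = 0.3) {
  stopifnot(inherits(params, "response_params"))
  if (!is.finite(t_end) || t_end <= 0) stop("t_end must be a positive number")
  if (!is.finite(smooth_span) || smooth_span <= 0 || smooth_span > 1) {
    stop("smooth_span must be in (0, 1]")
  }
  tp <- turning_points(params)
  grid <- 0:floor(t_end)
  raw <- stats::approx(tp$time, tp$value, xout = grid, rule = 2,
                       ties = "ordered")$y
  ## fixed absolute bandwidth (smooth_span of the 120-min reference window)
  f_eff <- min(1, smooth_span * 121 / length(grid))
  sm <- pmax(stats::lowess(grid, raw, f = f_eff, iter = 0, delta = 0)$y, 0)
  structure(list(times = grid, values = sm, params = params),
            class = "response_curve")
}

## Interpolated piecewise-linear (unsmoothed) value, used in tests.
raw_curve_value <- function(params, t) {
  tp <- turning_points(params)
  stats::approx(tp$time, tp$value, xout = t, rule = 2, ties = "ordered")$y
}

#' Evaluate a response curve at arbitrary times
#'
#' Linear interpolation between the 1-minute grid points; times must lie
#' within the grid range.
#'
#' @param curve a `response_curve` from [build_curve()].
#' @param t numeric vector of times in minutes.
#' @return Concentrations at `t`.
#' @export
curve_value <- function(curve, t) {
  stopifnot(inherits(curve, "response_curve"))
  rng <- range(curve$times)
  if (any(t < rng[1] | t > rng[2])) {
    stop("times outside the curve grid [", rng[1], ", ", rng[2], "]")
  }
  stats::approx(curve$times, curve$values, xout = t)$y
}

#' Area under a response profile
#'
#' Trapezoidal area under a set of (time, concentration) points.
#' `mode = "ground"` (AUC_G) integrates the concentration above zero;
#' `mode = "increase"` (AUC_I) integrates above the first sample's value
#' and may be negative.
#'
#' @param times strictly increasing sample times (min), length >= 2.
#' @param values concentrations at `times` (ng/µl).
#' @param mode `"ground"` or `"increase"`.
#' @return Area in ng·min/µl.
#' @examples
#' auc(c(0, 10, 20), c(0, 10, 0), mode = "ground")  # triangle: 100
#' @export
auc <- function(times, values, mode = c("ground", "increase")) {
  mode <- match.arg(mode)
  if (inherits(times, "response_curve")) {
    values <- times$values
    times <- times$times
  }
  if (length(times) < 2) stop("auc needs at least 2 points")
  if (length(times) != length(values)) {
    stop("times and values must have the same length")
  }
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  if (mode == "increase") values <- values - values[1]
  pracma::trapz(times, values)
}

#' Full event curves of a simulated dataset as a tidy table
#'
#' @param dataset an `observed_dataset` from [simulate_dataset()].
#' @return Tibble `(individual_id, event_id, time_min, value)` with one
#'   row per event and grid minute.
#' @export
curve_table <- function(dataset) {
  stopifnot(inherits(dataset, "observed_dataset"))
  key <- dataset$curve_key
  tibble::tibble(
    individual_id = rep(key$individual_id, each = length(dataset$grid)),
    event_id = rep(key$event_id, each = length(dataset$grid)),
    time_min = rep(dataset$grid, nrow(key)),
    value = as.numeric(t(dataset$curves))
  )
}

#' @export
print.response_curve <- function(x, ...) {
  cat("<response_curve> ", length(x$times), " grid points, max ",
      signif(max(x$values), 4), " ng/ul at t = ",
      x$times[which.max(x$values)], " min\n", sep = "")
  invisible(x)
}
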