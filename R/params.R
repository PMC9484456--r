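#' @keywords internal
"_PACKAGE"

## canonical parameter order used throughout the package
PARAM_NAMES <- c(
  "baseline", "onset_delay", "time_to_max", "max_value",
  "plateau_duration", "return_duration", "end_value"
)

#' True parameters of one acute hormonal response
#'
#' An acute glucocorticoid response is described phenomenologically by seven
#' parameters that fix the turning points of the concentration-time curve:
#' a flat pre-stressor baseline, a delayed onset of the rise, a linear rise
#' to the maximum, a plateau at the maximum, and a linear return to a
#' post-response recovery level.
#'
#' @param baseline pre-stressor concentration (ng/µl), >= 0.
#' @param onset_delay minutes after stressor onset at which the rise begins;
#'   0 <= `onset_delay` < `time_to_max`.
#' @param time_to_max minutes from stressor onset to the maximum.
#' @param max_value maximum concentration reached (ng/µl), >= `baseline`.
#' @param plateau_duration minutes spent at the maximum, >= 0.
#' @param return_duration minutes from the end of the plateau to the
#'   recovery level, > 0.
#' @param end_value post-response recovery concentration (ng/µl), >= 0.
#'
#' @return A `response_params` object (named list of the seven parameters).
#' @examples
#' p <- response_params(5, 3, 30, 25, 10, 20, 6)
#' turning_points(p)
#' @export
response_params <- function(baseline, onset_delay, time_to_max, max_value,
                            plateau_duration, return_duration, end_value) {
  p <- list(
    baseline = baseline, onset_delay = onset_delay,
    time_to_max = time_to_max, max_value = max_value,
    plateau_duration = plateau_duration, return_duration = return_duration,
    end_value = end_value
  )
  p <- lapply(p, as.numeric)
  bad <- validate_params(as.numeric(p))
  if (length(bad) > 0) {
    stop("invalid response parameters: ", paste(bad, collapse = "; "),
         call. = FALSE)
  }
  structure(p, class = "response_params")
}

## Vectorised validity check. `x` is a numeric vector of length 7 (one
## individual) or a matrix with 7 named columns. Returns a character vector
## of violated-constraint descriptions (length-7 input) or a logical vector
## of per-row validity (matrix input).
validate_params <- function(x) {
  if (is.matrix(x)) {
    ok <- apply(is.finite(x), 1L, all)
    ok & x[, "baseline"] >= 0 &
      x[, "max_value"] >= x[, "baseline"] &
      x[, "end_value"] >= 0 &
      x[, "onset_delay"] >= 0 &
      x[, "onset_delay"] < x[, "time_to_max"] &
      x[, "plateau_duration"] >= 0 &
      x[, "return_duration"] > 0
  } else {
    x <- stats::setNames(as.numeric(x), PARAM_NAMES)
    bad <- character(0)
    if (!all(is.finite(x))) {
      bad <- c(bad, paste0("non-finite: ",
                           paste(PARAM_NAMES[!is.finite(x)], collapse = ", ")))
    } else {
      if (x["baseline"] < 0) bad <- c(bad, "baseline must be >= 0")
      if (x["max_value"] < x["baseline"]) {
        bad <- c(bad, "max_value must be >= baseline")
      }
      if (x["end_value"] < 0) bad <- c(bad, "end_value must be >= 0")
      if (x["onset_delay"] < 0) bad <- c(bad, "onset_delay must be >= 0")
      if (x["onset_delay"] >= x["time_to_max"]) {
        bad <- c(bad, "onset_delay must be < time_to_max")
      }
      if (x["plateau_duration"] < 0) bad <- c(bad, "plateau_duration must be >= 0")
      if (x["return_duration"] <= 0) bad <- c(bad, "return_duration must be > 0")
    }
    bad
  }
}

#' Turning points of a response curve
#'
#' Maps the seven parameters to the five (time, concentration) turning
#' points of the piecewise-linear response skeleton: start of baseline,
#' end of baseline (onset), peak, end of plateau, and recovery.
#'
#' @param params a [response_params()] object.
#' @return A tibble with columns `time` (min) and `value` (ng/µl), 5 rows,
#'   times strictly increasing.
#' @export
turning_points <- function(params) {
  stopifnot(inherits(params, "response_params"))
  p <- unlist(params)
  if (p[["onset_delay"]] <= 0) {
    stop("onset_delay must be > 0: the baseline segment needs positive width",
         call. = FALSE)
  }
  tibble::tibble(
    time = c(0,
             p[["onset_delay"]],
             p[["time_to_max"]],
             p[["time_to_max"]] + p[["plateau_duration"]],
             p[["time_to_max"]] + p[["plateau_duration"]] + p[["return_duration"]]),
    value = c(p[["baseline"]], p[["baseline"]], p[["max_value"]],
              p[["max_value"]], p[["end_value"]])
  )
}

#' @export
print.response_params <- function(x, ...) {
  cat("<response_params>\n")
  print(unlist(x))
  invisible(x)
}
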