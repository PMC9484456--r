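#' Three-panel summary plot of a simulation run
#'
#' (A) the downsampled measured dataset, (B) the full observed response
#' curve for every event, (C) the rank order of each individual's level at
#' every minute. Dashed vertical lines mark the fixed sampling times when
#' the design has them.
#'
#' @param dataset an `observed_dataset` from [simulate_dataset()].
#' @return A patchwork object stacking the three panels if the patchwork
#'   package is installed, otherwise a named list of the three ggplots.
#' @export
plot_simulation_summary <- function(dataset) {
  stopifnot(inherits(dataset, "observed_dataset"))
  obs <- dataset$observed
  obs$individual_id <- factor(obs$individual_id)
  vlines <- if (dataset$design$kind == "fixed") dataset$design$fixed_times
  add_vlines <- function(p) {
    if (!is.null(vlines)) {
      p + ggplot2::geom_vline(xintercept = vlines, linetype = "dashed",
                              colour = "grey40")
    } else p
  }
  p_a <- add_vlines(
    ggplot2::ggplot(obs, ggplot2::aes(x = time_min, y = value,
                                      colour = individual_id,
                                      group = interaction(individual_id,
                                                          event_id))) +
      ggplot2::geom_point() + ggplot2::geom_line(alpha = 0.5) +
      ggplot2::labs(title = "Downsampled measurements",
                    x = "Time (min)", y = "Concentration (ng/µl)") +
      ggplot2::theme_minimal() + ggplot2::theme(legend.position = "none"))

  key <- dataset$curve_key
  long <- tibble::tibble(
    individual_id = factor(rep(key$individual_id, each = length(dataset$grid))),
    event_id = rep(key$event_id, each = length(dataset$grid)),
    time_min = rep(dataset$grid, nrow(key)),
    value = as.numeric(t(dataset$curves))
  )
  p_b <- add_vlines(
    ggplot2::ggplot(long, ggplot2::aes(x = time_min, y = value,
                                       colour = individual_id,
                                       group = interaction(individual_id,
                                                           event_id))) +
      ggplot2::geom_line(alpha = 0.7) +
      ggplot2::labs(title = "Full observed response curves",
                    x = "Time (min)", y = "Concentration (ng/µl)") +
      ggplot2::theme_minimal() + ggplot2::theme(legend.position = "none"))

  first_event <- long[long$event_id == 1, ]
  ranks <- dplyr::mutate(dplyr::group_by(first_event, time_min),
                         rank = rank(-value, ties.method = "first"))
  p_c <- add_vlines(
    ggplot2::ggplot(ranks, ggplot2::aes(x = time_min, y = rank,
                                        colour = individual_id,
                                        group = individual_id)) +
      ggplot2::geom_line(alpha = 0.7) +
      ggplot2::scale_y_reverse() +
      ggplot2::labs(title = "Rank order through time",
                    x = "Time (min)", y = "Rank (1 = highest)") +
      ggplot2::theme_minimal() + ggplot2::theme(legend.position = "none"))

  if (requireNamespace("patchwork", quietly = TRUE)) {
    p_a / p_b / p_c
  } else {
    list(downsampled = p_a, curves = p_b, ranks = p_c)
  }
}

#' @importFrom ggplot2 ggplot
NULL
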