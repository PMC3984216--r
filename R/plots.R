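# ggplot2 figures for runs and comparisons.

#' Plot trajectories of one or more scenarios
#'
#' Faceted time-series panels in the style of the model's headline output
#' figure: bicycle mode share, annual fatal + serious cyclist injuries, the
#' injury rate per 1,000 cyclists and commuting air-pollution mortality.
#'
#' @param ... One or more `cyclesim_run` objects (or a single list of them).
#' @param outputs Trajectory columns to facet.
#' @return A ggplot object.
#' @export
plot_scenarios <- function(...,
                           outputs = c("share_bicycle", "fatal_plus_serious",
                                       "injury_rate_per_1000", "air_deaths")) {
  runs <- list(...)
  if (length(runs) == 1 && !inherits(runs[[1]], "cyclesim_run")) {
    runs <- runs[[1]]
  }
  df <- purrr::map_dfr(runs, function(r) {
    dplyr::mutate(r$trajectory,
                  fatal_plus_serious = .data$fatal + .data$serious,
                  scenario = r$scenario)
  })
  long <- tidyr::pivot_longer(
    dplyr::select(df, "scenario", "year", dplyr::all_of(outputs)),
    -c("scenario", "year"), names_to = "output", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$year, y = .data$value,
                                     colour = .data$scenario)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~output, scales = "free_y") +
    ggplot2::labs(x = "year", y = NULL, colour = "scenario") +
    ggplot2::theme_minimal()
}

#' @rdname plot_scenarios
#' @param object A `cyclesim_run`.
#' @export
autoplot.cyclesim_run <- function(object, ...) {
  plot_scenarios(object)
}

#' Plot a Monte Carlo ensemble
#'
#' Distribution of final-year outputs across the ensemble.
#'
#' @param object A `cyclesim_mc`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cyclesim_mc <- function(object, ...) {
  ggplot2::ggplot(object$final, ggplot2::aes(x = .data$value)) +
    ggplot2::geom_histogram(bins = 30) +
    ggplot2::facet_wrap(~output, scales = "free") +
    ggplot2::labs(x = "final-year value", y = "runs",
                  title = paste(object$scenario, "ensemble")) +
    ggplot2::theme_minimal()
}

#' Plot monetized cumulative outcomes of a comparison
#'
#' @param object A `cyclesim_comparison`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cyclesim_comparison <- function(object, ...) {
  df <- dplyr::filter(object$monetized, !is.na(.data$value_nzd_m))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$value_nzd_m,
                                   y = stats::reorder(.data$category,
                                                      .data$value_nzd_m))) +
    ggplot2::geom_col() +
    ggplot2::geom_vline(xintercept = 0, linewidth = 0.3) +
    ggplot2::labs(x = "$NZ million (negative = saving)", y = NULL,
                  title = paste(object$run$scenario, "vs baseline, 2012-2051")) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
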