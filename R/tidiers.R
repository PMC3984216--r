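# broom-style tidiers and ggplot2 autoplot methods for the result objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a simulation run into long format
#'
#' @param x A `cyclesim_run`.
#' @param outputs Optional character vector restricting the columns.
#' @param ... Unused.
#' @return Tibble: `scenario`, `year`, `output`, `value`.
#' @export
tidy.cyclesim_run <- function(x, outputs = NULL, ...) {
  traj <- x$trajectory
  if (!is.null(outputs)) {
    traj <- dplyr::select(traj, "year", dplyr::all_of(outputs))
  }
  tidyr::pivot_longer(traj, -"year", names_to = "output",
                      values_to = "value") |>
    dplyr::mutate(scenario = x$scenario, .before = 1)
}

#' One-row summary of a simulation run
#'
#' @param x A `cyclesim_run`.
#' @param ... Unused.
#' @return Tibble with the scenario, grid and headline end-of-run outcomes.
#' @export
glance.cyclesim_run <- function(x, ...) {
  last <- x$trajectory[nrow(x$trajectory), ]
  tibble::tibble(
    scenario = x$scenario,
    start_year = x$grid$start_year,
    end_year = x$grid$end_year,
    dt = x$grid$dt,
    share_bicycle_final = last$share_bicycle,
    share_light_vehicle_final = last$share_light_vehicle,
    injury_rate_final = last$injury_rate_per_1000,
    perceived_safe_final = last$perceived_safe,
    ghg_per_capita_final = last$ghg_per_capita_t
  )
}

#' Tidy a scenario-vs-baseline comparison
#'
#' @param x A `cyclesim_comparison`.
#' @param ... Unused.
#' @return The monetized cumulative-outcome tibble with a `scenario` column.
#' @export
tidy.cyclesim_comparison <- function(x, ...) {
  dplyr::mutate(x$monetized, scenario = x$run$scenario, .before = 1)
}

#' One-row summary of a comparison
#'
#' @param x A `cyclesim_comparison`.
#' @param ... Unused.
#' @return Tibble: scenario, infrastructure cost, net benefit, BCR.
#' @export
glance.cyclesim_comparison <- function(x, ...) {
  tibble::tibble(
    scenario = x$run$scenario,
    infrastructure_cost_nzd_m = infrastructure_cost(x$run$config),
    net_benefit_nzd_m = x$net_benefit_nzd_m,
    bcr = x$bcr
  )
}

#' Tidy a Monte Carlo ensemble
#'
#' @param x A `cyclesim_mc`.
#' @param ... Unused.
#' @return The per-draw final-year output tibble.
#' @export
tidy.cyclesim_mc <- function(x, ...) {
  dplyr::mutate(x$final, scenario = x$scenario, .before = 1)
}

#' @rdname tidy.cyclesim_mc
#' @export
glance.cyclesim_mc <- function(x, ...) {
  dplyr::mutate(x$summary, scenario = x$scenario, n = nrow(x$draws),
                seed = x$seed, .before = 1)
}
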