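# Cumulative scenario-vs-baseline accounting, monetization and benefit-cost
# ratios. Sign convention throughout: negative = saving relative to
# business-as-usual (extra cyclist injuries are positive, averted deaths and
# saved fuel are negative).

CBA_CATEGORIES <- c(
  "cyclist_fatalities", "cyclist_serious_injuries", "car_occupant_fatalities",
  "air_mortality", "air_hospitalisations", "air_copd", "air_cancers",
  "restricted_activity_days", "pa_mortality", "ghg_megatons", "fuel_nzd_m",
  "lvkt_billion_km"
)

# trapezoid integral of an annual-rate series sampled on the grid, restricted
# to [from, to]
trapz_years <- function(year, rate, from, to) {
  keep <- year >= from & year <= to
  y <- year[keep]; r <- rate[keep]
  sum(diff(y) * (utils::head(r, -1) + utils::tail(r, -1)) / 2)
}

#' Cumulative scenario-minus-baseline outcomes
#'
#' Time-integrates (trapezoid on the simulation grid) the difference between
#' a scenario trajectory and its baseline over the policy window (2012 to
#' the end of the run) for every outcome feeding the benefit-cost analysis.
#' Physical-activity mortality is computed here from the lead-time-lagged
#' difference in bicycle commuters between the two runs. A nonzero
#' configured discount rate exponentially down-weights later years
#' (default 0: benefits and harms are not discounted).
#'
#' @param run A scenario `cyclesim_run`.
#' @param baseline The baseline `cyclesim_run` on the identical grid.
#' @param from First year of accumulation (default: rollout start).
#' @return Tibble with `category` and `value` (negative = saving): cyclist
#'   fatalities and serious injuries, car-occupant fatalities, air-pollution
#'   mortality/hospitalisations/COPD/cancers/restricted activity days,
#'   physical-activity mortality, greenhouse gases (megatons), fuel ($NZ
#'   million) and light-vehicle kilometres (billion km).
#' @export
accumulate_outcomes <- function(run, baseline, from = NULL) {
  if (!identical(run$grid$times, baseline$grid$times)) {
    stop("accumulate_outcomes: scenario and baseline grids differ", call. = FALSE)
  }
  from <- from %||% run$config$policy$rollout$start_year
  to <- run$grid$end_year
  s <- run$trajectory
  b <- baseline$trajectory
  year <- s$year
  disc <- (1 + run$config$cba$discount_rate)^(-(pmax(year, from) - from))

  dd <- function(col) (s[[col]] - b[[col]]) * disc
  averted <- deaths_averted(year,
                            s$cyclists_effective - b$cyclists_effective,
                            run$config) * disc
  acc <- function(rate) trapz_years(year, rate, from, to)

  tibble::tibble(
    category = CBA_CATEGORIES,
    value = c(
      acc(dd("fatal")),
      acc(dd("serious")),
      acc(dd("car_occupant_fatalities")),
      acc(dd("air_deaths")),
      acc(dd("air_hospitalisations")),
      acc(dd("air_copd")),
      acc(dd("air_cancers")),
      acc(dd("air_rad")),
      -acc(averted),
      acc(dd("ghg_total_t")) / 1e6,
      acc(dd("fuel_cost_nzd")) / 1e6,
      acc(dd("lv_vkt")) / 1e9
    )
  )
}

#' Monetize cumulative outcomes
#'
#' Multiplies each outcome count by its unit value, expressed throughout in
#' $NZ million: $3.1M per fatality (cyclist, car occupant, or
#' physical-activity death), $0.325M per serious cyclist injury, $0.75M per
#' air-pollution death or cancer, $0.003M per hospitalisation, $0.075M per
#' COPD admission, $98 per restricted activity day and $40 per metric ton of
#' CO2-equivalent. Fuel is already monetary; light-vehicle kilometres carry
#' no unit value and are reported with `value_nzd_m = NA`. Signs are
#' preserved (negative = saving). No discounting or inflation is applied.
#'
#' @param outcomes Tibble from [accumulate_outcomes()] (or any tibble with
#'   `category` and `value` using the same category names).
#' @param config A [scenario_config()] (or a list with `cba$unit_values`).
#' @return The input tibble with a `value_nzd_m` column appended.
#' @examples
#' uv <- scenario_config()
#' monetize(tibble::tibble(category = "cyclist_fatalities", value = 200), uv)
#' @export
monetize <- function(outcomes, config) {
  uv <- config$cba$unit_values
  per_unit <- c(
    cyclist_fatalities = uv$cyclist_fatalities,
    cyclist_serious_injuries = uv$cyclist_serious_injuries,
    car_occupant_fatalities = uv$car_occupant_fatalities,
    air_mortality = uv$air_mortality,
    air_hospitalisations = uv$air_hospitalisations,
    air_copd = uv$air_copd,
    air_cancers = uv$air_cancers,
    restricted_activity_days = uv$restricted_activity_days,
    pa_mortality = uv$pa_mortality,
    ghg_megatons = uv$ghg_per_tonne * 1e6,  # $M per megaton
    fuel_nzd_m = 1,
    lvkt_billion_km = NA_real_
  )
  unknown <- setdiff(outcomes$category, names(per_unit))
  if (length(unknown) > 0) {
    stop("monetize: no unit value for category: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  dplyr::mutate(outcomes,
                value_nzd_m = unname(.data$value * per_unit[.data$category]))
}

#' Net benefit and benefit-cost ratio
#'
#' Net benefit is minus the sum of the monetized categories (so savings are
#' positive); the benefit-cost ratio divides it by the infrastructure cost.
#' Undiscounted and uninflated.
#'
#' @param monetized Tibble from [monetize()].
#' @param infra_cost_nzd_m Infrastructure cost, $NZ million.
#' @return List with `net_benefit` ($NZ million) and `bcr` (`NA` when the
#'   cost is zero but benefits are not — an undefined ratio, e.g. the
#'   baseline compared with itself yields `net_benefit = 0, bcr = 0`).
#' @export
benefit_cost_ratio <- function(monetized, infra_cost_nzd_m) {
  vals <- monetized$value_nzd_m[!is.na(monetized$value_nzd_m)]
  net <- -sum(vals)
  bcr <- if (infra_cost_nzd_m > 0) {
    net / infra_cost_nzd_m
  } else if (abs(net) < 1e-9) 0 else NA_real_
  list(net_benefit = net, bcr = bcr)
}

#' Summary table across scenarios
#'
#' Runs (or re-uses) the four active scenarios against the shared baseline
#' and assembles the cumulative-outcome table: one row per outcome category,
#' one pair of columns (count, monetized $NZ million) per scenario, plus
#' mode-share, net-benefit and benefit-cost summary rows.
#'
#' @param scenarios Character vector of active scenario names.
#' @param grid Optional [time_grid()].
#' @return A tibble in long form: `scenario`, `category`, `value`,
#'   `value_nzd_m`, plus summary categories `cycling_share_2051`,
#'   `lv_share_2051`, `perceived_safe_2040`, `infrastructure_cost_nzd_m`,
#'   `net_benefit_nzd_m` and `bcr`.
#' @export
scenario_summary <- function(scenarios = c("rcn", "asbl", "ser", "asbl_ser"),
                             grid = NULL) {
  baseline <- run_scenario("baseline", grid = grid)
  purrr::map_dfr(scenarios, function(sc) {
    cmp <- compare_to_baseline(sc, grid = grid, baseline = baseline)
    traj <- cmp$run$trajectory
    at <- function(yr, col) traj[[col]][which.min(abs(traj$year - yr))]
    extra <- tibble::tibble(
      category = c("cycling_share_2051", "lv_share_2051", "perceived_safe_2040",
                   "infrastructure_cost_nzd_m", "net_benefit_nzd_m", "bcr"),
      value = c(at(2051, "share_bicycle"), at(2051, "share_light_vehicle"),
                at(2040, "perceived_safe"),
                infrastructure_cost(cmp$run$config),
                cmp$net_benefit_nzd_m, cmp$bcr),
      value_nzd_m = NA_real_
    )
    dplyr::bind_rows(
      dplyr::mutate(cmp$monetized, scenario = sc, .before = 1),
      dplyr::mutate(extra, scenario = sc, .before = 1)
    )
  })
}
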