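# Air-pollution burden of disease, greenhouse-gas CO2-equivalents and fuel
# cost of commuter light-vehicle kilometres. The regional emission and
# burden models behind the original estimates are represented by declining
# exponential trend curves calibrated to the published 2007 per-commuter
# emissions anchor; removing a commuting vehicle-km is assumed equivalent to
# removing any light-vehicle km over a 24-hour period.

#' Fleet emission factor at a given year
#'
#' Business-as-usual technology improvement: exponential decline from the
#' 1991 factor. Particulate-proxy (PM10) and greenhouse-gas factors decline
#' at different configured rates.
#'
#' @param t Year(s).
#' @param gas One of `"co2"`, `"co"`, `"ch4"`, `"n2o"`, `"pm10"`. `"pm10"`
#'   returns the relative factor (1 at 1991) driving the burden-of-disease
#'   scaling; the others return g/km.
#' @param cfg A [scenario_config()].
#' @return Emission factor(s).
#' @export
emission_factor <- function(t, gas, cfg) {
  e <- cfg$env
  dt <- t - cfg$grid$start_year
  if (gas == "pm10") return(exp(-e$ef_decline_pm10 * dt))
  e$emission_factors_1991[[gas]] * exp(-e$ef_decline_ghg * dt)
}

#' Air-pollution burden of disease attributable to commuting
#'
#' Scales the 1991 baseline annual counts by relative vehicle kilometres,
#' the relative fleet emission factor and relative exposed population:
#' `count_o(t) = base_o * (vkt/vkt_1991) * (EF(t)/EF(1991)) * pop_scale`.
#' Linear in each factor.
#'
#' @param t Year(s).
#' @param vkt Light-vehicle km/yr at `t`.
#' @param vkt_1991 Light-vehicle km/yr at baseline.
#' @param pop_scale Relative exposed population (1 at 1991).
#' @param cfg A [scenario_config()].
#' @return Tibble with one row per `t`: `deaths`, `hospitalisations`, `copd`,
#'   `cancers`, `restricted_activity_days`.
#' @export
air_pollution_burden <- function(t, vkt, vkt_1991, pop_scale, cfg) {
  stopifnot(all(vkt >= 0), vkt_1991 > 0)
  base <- cfg$env$bod_baseline_1991
  scale <- (vkt / vkt_1991) * emission_factor(t, "pm10", cfg) * pop_scale
  tibble::tibble(
    deaths = base$deaths * scale,
    hospitalisations = base$hospitalisations * scale,
    copd = base$copd * scale,
    cancers = base$cancers * scale,
    restricted_activity_days = base$restricted_activity_days * scale
  )
}

#' Greenhouse-gas emissions of the commuting fleet
#'
#' Sums CO2, CO, CH4 and N2O per-km emissions weighted by 100-year global
#' warming potentials. Per-capita emissions are expressed per commuting
#' person, the denominator consistent with the published 2007 anchor of
#' roughly 3.1 t CO2-equivalent per capita from commuting.
#'
#' @param t Year(s).
#' @param vkt Light-vehicle km/yr.
#' @param commuters Commuting population (persons).
#' @param cfg A [scenario_config()].
#' @return Tibble: `total_t` (metric tons/yr), `per_capita_t`
#'   (tons/person/yr).
#' @export
ghg_co2eq <- function(t, vkt, commuters, cfg) {
  stopifnot(all(commuters > 0))
  gwp <- cfg$env$gwp
  g_per_km <- Reduce(`+`, lapply(names(gwp), function(gas) {
    emission_factor(t, gas, cfg) * gwp[[gas]]
  }))
  total <- vkt * g_per_km / 1e6  # g -> metric tons
  tibble::tibble(total_t = total, per_capita_t = total / commuters)
}

#' Mix-weighted pump fuel price
#'
#' @param t Year(s).
#' @param cfg A [scenario_config()].
#' @return $NZ per litre.
#' @export
fuel_price <- function(t, cfg) {
  e <- cfg$env
  growth <- (1 + e$fuel_price_growth)^(t - cfg$grid$start_year)
  (e$petrol_fraction * e$fuel_price_1991$petrol +
     (1 - e$petrol_fraction) * e$fuel_price_1991$diesel) * growth
}

#' Fuel cost of light-vehicle kilometres
#'
#' `cost = vkt * litres/km (t) * mix-weighted price (t)`. Fuel consumption
#' per km improves exponentially with the fleet. Savings from averted
#' kilometres are differences of this quantity, so a negative `vkt`
#' difference (more driving) carries its sign through.
#'
#' @param t Year(s).
#' @param vkt Light-vehicle km/yr (may be a difference; sign preserved).
#' @param cfg A [scenario_config()].
#' @return $NZ per year.
#' @export
fuel_cost <- function(t, vkt, cfg) {
  e <- cfg$env
  l_per_km <- e$fuel_l_per_km_1991 *
    exp(-e$fuel_efficiency_decline * (t - cfg$grid$start_year))
  vkt * l_per_km * fuel_price(t, cfg)
}
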