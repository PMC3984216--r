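# Commuter population growth and the relative-utility mode-share model with
# delayed perceptions, producing light-vehicle kilometres travelled (LVKT).

#' Project the commuting population
#'
#' Exponential growth at the constant annual rate that yields the stated
#' total growth over the 60-year run: commuters grow like the regional
#' population, +40% from a 400,000 baseline by default.
#'
#' @param t Year(s).
#' @param cfg A [scenario_config()].
#' @return Commuters (persons) at `t`.
#' @examples
#' project_commuters(1991, scenario_config()) # 400000
#' @export
project_commuters <- function(t, cfg) {
  d <- cfg$demand
  d$baseline_commuters *
    (1 + d$growth_total)^((t - cfg$grid$start_year) / d$growth_reference_years)
}

#' Mode shares from smoothed perceptions
#'
#' Relative-utility share model: each mode's utility is its baseline share
#' weighted by its (smoothed) attractiveness index, and shares are utilities
#' normalized to 1 — a logit-equivalent form whose alternative-specific
#' constants reproduce the baseline shares when all indices equal 1.
#' The bicycle share is then capped at the cyclable fraction of trips
#' (<= 6 km) and the walk share at the walkable fraction (<= 2 km), with any
#' excess re-normalized over the uncapped modes.
#'
#' @param attractiveness Named numeric vector of positive attractiveness
#'   indices for `light_vehicle`, `bicycle`, `walk`, `public_transport`.
#' @param cfg A [scenario_config()].
#' @return Named numeric vector of mode shares summing to 1.
#' @examples
#' cfg <- scenario_config()
#' a <- c(light_vehicle = 1, bicycle = 1, walk = 1, public_transport = 1)
#' mode_shares_from_perceptions(a, cfg) # the baseline shares
#' @export
mode_shares_from_perceptions <- function(attractiveness, cfg) {
  base <- unlist(cfg$demand$base_shares)[MODES]
  a <- attractiveness[MODES]
  if (any(is.na(a)) || any(a < 0)) {
    stop("mode_shares_from_perceptions: attractiveness must be nonnegative and ",
         "named for all four modes", call. = FALSE)
  }
  u <- base * a
  if (sum(u) <= 0) {
    stop("mode_shares_from_perceptions: all utilities are zero (degenerate input)",
         call. = FALSE)
  }
  shares <- u / sum(u)
  caps <- c(bicycle = cfg$demand$cyclable_fraction,
            walk = cfg$demand$walkable_fraction)
  # cap bicycling and walking at their distance-eligible trip pools and
  # redistribute the excess over the uncapped modes, preserving the sum
  for (pass in 1:2) {
    over <- intersect(names(caps)[shares[names(caps)] > caps], names(shares))
    if (length(over) == 0) break
    excess <- sum(shares[over] - caps[over])
    shares[over] <- caps[over]
    free <- setdiff(MODES, names(caps)[shares[names(caps)] >= caps])
    shares[free] <- shares[free] + excess * shares[free] / sum(shares[free])
  }
  shares / sum(shares)
}

#' Annual light-vehicle kilometres travelled by commuters
#'
#' `VKT = commuters * lv_share / occupancy * annual_trips * median_trip_km`.
#' Occupancy converts person-trips to vehicle-trips (a share of light-vehicle
#' commuters are passengers).
#'
#' @param lv_share Light-vehicle mode share.
#' @param commuters Commuting population (persons).
#' @param cfg A [scenario_config()].
#' @return km per year.
#' @export
annual_lv_vkt <- function(lv_share, commuters, cfg) {
  d <- cfg$demand
  if (d$lv_occupancy <= 0) {
    stop("annual_lv_vkt: lv_occupancy must be positive", call. = FALSE)
  }
  commuters * lv_share / d$lv_occupancy * d$annual_commute_trips *
    d$median_lv_commute_km
}

#' Advance the smoothed mode-perception indices
#'
#' Stated preference responds to perception changes with a one-year average
#' delay before revealed mode share follows; the smoothed indices are the
#' corresponding first-order-delay stocks, advanced one Euler step toward the
#' instantaneous (raw) indices.
#'
#' @param smoothed Named numeric vector of current smoothed indices.
#' @param raw Named numeric vector of instantaneous indices (same names).
#' @param dt Step size in years.
#' @param cfg A [scenario_config()].
#' @return Updated smoothed indices.
#' @export
update_perceptions <- function(smoothed, raw, dt, cfg) {
  if (any(raw <= 0)) {
    stop("update_perceptions: perception indices must be positive", call. = FALSE)
  }
  delay_step(smoothed, raw, cfg$demand$preference_delay_years, dt)
}

# Instantaneous perception indices, before the one-year preference delay.
# The bicycle index is the perception of bicycling as a way to commute times
# the perceived-safety ratio raised to its elasticity (safety is the dominant
# stated barrier to cycling, so utility responds steeply to it); the
# light-vehicle index carries the historical convenience trend (motorway-era
# car dominance, flat after 2012) and any policy-driven convenience
# reduction. Walking and public transport have no dynamic perceptions here
# (their co-benefits are out of scope).
raw_perception_indices <- function(t, perceived_safe, eff, cfg) {
  d <- cfg$demand
  if (eff$commute_mult <= 0 || eff$lv_convenience_mult <= 0) {
    stop("raw_perception_indices: policy multipliers must be positive",
         call. = FALSE)
  }
  lv_trend <- (1 + d$lv_trend_growth)^(min(t, d$lv_trend_end) - cfg$grid$start_year)
  bike_trend <- (1 - d$bike_trend_decline)^(min(t, d$bike_trend_end) -
                                              cfg$grid$start_year)
  safety_ratio <- perceived_safe / d$perceived_safe_baseline
  c(light_vehicle = lv_trend * eff$lv_convenience_mult,
    bicycle = bike_trend * eff$commute_mult * safety_ratio^d$safety_elasticity,
    walk = 1,
    public_transport = 1)
}

# Perception indices -> attractiveness. The bicycle index already carries its
# safety elasticity; habitual car use responds to convenience with its own
# (lower) elasticity.
attractiveness_from_indices <- function(indices, cfg) {
  e <- c(light_vehicle = cfg$demand$perception_elasticity_lv,
         bicycle = 1, walk = 1, public_transport = 1)
  indices[MODES]^e[MODES]
}
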