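# Policy scenarios: the S-shaped rollout fraction and the translation of the
# published intervention effect sizes into the multipliers consumed by the
# demand and injury sectors.
#
# Scenarios: rcn (on-road lanes on 46% of arterials, off-road path expansion
# from 10 to 25 km per 100,000 population, a negligible footprint of shared
# bus/bike lanes), asbl (segregated lanes with intersection treatments on all
# arterials), ser (low-speed bicycle-friendly redesign of local streets) and
# their combination. All effects scale with the rollout fraction p.

#' Rollout fraction of a policy scenario
#'
#' S-shaped implementation beginning in 2012, essentially complete by 2040
#' (regional cycle network) or 2050 (all other active scenarios). The
#' baseline scenario has no rollout (always 0).
#'
#' @param t Year(s).
#' @param cfg A [scenario_config()].
#' @return Fraction(s) in `[0, 1]`; exactly 0 before 2012.
#' @export
rollout_fraction <- function(t, cfg) {
  if (cfg$scenario == "baseline") return(rep(0, length(t)))
  curve <- rollout_curve(cfg$policy$rollout$start_year,
                         cfg$policy$rollout$completion_year)
  p <- s_curve(t, curve)
  p[t < curve$start_year] <- 0
  p
}

#' Region-wide collision relative risk of an infrastructure component
#'
#' A component with coverage ceiling `coverage` (fraction of its road class)
#' and an effective per-treated-km relative risk `rr_eff` yields, at rollout
#' fraction `p`, a class-level multiplier `1 - p * coverage * (1 - rr_eff)`.
#' Where midblock and intersection relative risks differ, `rr_eff` is their
#' mix weighted by the midblock share of collisions.
#'
#' @param p Rollout fraction in `[0, 1]`.
#' @param coverage Fraction of the road class treated at full rollout.
#' @param rr_mid,rr_int Relative risks for midblock and intersection
#'   collisions (equal for single-RR components).
#' @param midblock_share Fraction of collisions occurring midblock.
#' @return Region-level collision relative risk for the class.
#' @examples
#' network_collision_rr(1, 1, 0.72, 0.8, 0.5)   # segregated lanes: 0.76
#' network_collision_rr(1, 0.46, 0.9)           # on-road lanes: 0.954
#' @export
network_collision_rr <- function(p, coverage, rr_mid, rr_int = rr_mid,
                                 midblock_share = 0.5) {
  stopifnot(p >= 0, p <= 1, coverage >= 0)
  rr_eff <- midblock_share * rr_mid + (1 - midblock_share) * rr_int
  1 - p * coverage * (1 - rr_eff)
}

#' Translate a scenario's rollout fraction into model multipliers
#'
#' Computes every channel through which the active policy acts at rollout
#' fraction `p`: perception-of-safety and perception-of-commuting multipliers
#' for bicycling, the light-vehicle convenience multiplier, per-road-class
#' collision relative risks, the local mean-speed reduction, the local
#' vehicle-volume multiplier and the local share of cycling distance.
#' Perception effects from distinct components compose multiplicatively;
#' self-explaining-road effects are linear in `p` up to their published
#' ceilings; the combined scenario is the composition of its two parts.
#'
#' @param p Rollout fraction in `[0, 1]`.
#' @param cfg A [scenario_config()].
#' @return Named list: `safety_mult`, `commute_mult`, `lv_convenience_mult`,
#'   `collision_rr` (named vector, local/arterial), `speed_delta_local`
#'   (km/h, nonpositive), `volume_mult_local`, `local_cycle_share`.
#' @examples
#' apply_policy_effects(0, scenario_config("asbl"))$commute_mult # 1
#' apply_policy_effects(1, scenario_config("ser"))$speed_delta_local # -15
#' @export
apply_policy_effects <- function(p, cfg) {
  stopifnot(length(p) == 1, p >= 0, p <= 1)
  scen <- cfg$scenario
  eff <- list(safety_mult = 1, commute_mult = 1, lv_convenience_mult = 1,
              collision_rr = c(local = 1, arterial = 1),
              speed_delta_local = 0, volume_mult_local = 1,
              local_cycle_share = cfg$injury$local_cycle_share)
  if (scen == "baseline" || p == 0) return(eff)
  mb <- cfg$injury$midblock_share

  if (scen %in% c("rcn")) {
    r <- cfg$policy$rcn
    # on-road marked lanes: increments accrue per 10% of the arterial
    # network treated, i.e. per unit of p * coverage * 10
    eff$safety_mult <- eff$safety_mult *
      (1 + r$onroad$safety_inc * 10 * p * r$onroad$coverage)
    eff$commute_mult <- eff$commute_mult *
      (1 + r$onroad$commute_inc * 10 * p * r$onroad$coverage)
    eff$collision_rr[["arterial"]] <- eff$collision_rr[["arterial"]] *
      network_collision_rr(p, r$onroad$coverage, r$onroad$rr,
                           midblock_share = mb)
    # off-road shared paths: perception effects scale with doublings of
    # km per 100,000 population; no collision effect (RR = 1)
    km <- r$offroad$km_per_100k_base +
      p * (r$offroad$km_per_100k_full - r$offroad$km_per_100k_base)
    doublings <- log2(km / r$offroad$km_per_100k_base)
    eff$commute_mult <- eff$commute_mult *
      (1 + r$offroad$commute_inc_per_doubling * doublings)
    eff$safety_mult <- eff$safety_mult *
      (1 + r$offroad$safety_inc_per_doubling * doublings)
    # shared bus/bike lanes: RR 1.0 at mean lane width on 0.04% of the
    # network; no net effect
  }

  if (scen %in% c("asbl", "asbl_ser")) {
    a <- cfg$policy$asbl
    eff$safety_mult <- eff$safety_mult * (1 + a$safety_inc * 10 * p * a$coverage)
    eff$commute_mult <- eff$commute_mult * (1 + a$commute_inc * 10 * p * a$coverage)
    eff$collision_rr[["arterial"]] <- eff$collision_rr[["arterial"]] *
      network_collision_rr(p, a$coverage, a$rr_mid, a$rr_int, mb)
  }

  if (scen %in% c("ser", "asbl_ser")) {
    s <- cfg$policy$ser
    eff$safety_mult <- eff$safety_mult * (1 + s$safety_boost_max * p)
    eff$commute_mult <- eff$commute_mult * (1 + s$commute_boost_max * p)
    eff$lv_convenience_mult <- eff$lv_convenience_mult *
      (1 - s$lv_convenience_reduction_max * p)
    eff$speed_delta_local <- eff$speed_delta_local - s$max_speed_reduction_kmh * p
    eff$volume_mult_local <- eff$volume_mult_local * (1 - s$max_volume_reduction * p)
    eff$local_cycle_share <- cfg$injury$local_cycle_share +
      p * (s$local_cycle_share_full - cfg$injury$local_cycle_share)
  }
  eff
}

#' Infrastructure cost of a scenario
#'
#' Total (undiscounted, uninflated) cost in $NZ million.
#' @param cfg A [scenario_config()].
#' @return Cost in $NZ million.
#' @export
infrastructure_cost <- function(cfg) {
  cfg$policy$infrastructure_cost_nzd_m[[cfg$scenario]]
}
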