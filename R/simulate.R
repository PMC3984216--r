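# The integrated model: one step couples demand (mode shares from delayed
# perceptions), injury (collisions, severity, safety-in-numbers), and the
# environmental/health outcome sectors, closing the balancing loop in which
# injuries depress the sense of safety and hence the bicycle share.

# Precompute run-level context: 1991 operating points and calibrated curves.
# The sense-of-safety curve is anchored to the run's own 1991 injury counts,
# so the feedback responds to counts relative to the calibration era.
init_context <- function(cfg) {
  d <- cfg$demand
  commuters0 <- d$baseline_commuters
  shares0 <- unlist(d$base_shares)[MODES]
  vkt0 <- annual_lv_vkt(shares0[["light_vehicle"]], commuters0, cfg)
  cyclists0 <- shares0[["bicycle"]] * commuters0
  sinm0 <- sin_multiplier(shares0[["bicycle"]], cfg$injury$sin)
  coll0 <- annual_collisions(cyclists0, cfg$injury$local_cycle_share,
                             c(local = 1, arterial = 1),
                             c(local = 1, arterial = 1),
                             sinm0, 0, cfg)
  sev0 <- severity_split(coll0, c(local = cfg$injury$mean_speed_local,
                                  arterial = cfg$injury$mean_speed_arterial), cfg)
  baseline_counts <- sev0$fatal + sev0$serious
  list(
    commuters0 = commuters0, vkt0 = vkt0, cyclists0 = cyclists0,
    baseline_counts = baseline_counts,
    safety_curve = build_safety_curve(baseline_counts, cfg),
    speeds = c(local = cfg$injury$mean_speed_local,
               arterial = cfg$injury$mean_speed_arterial)
  )
}

# One Euler step: compute all auxiliaries at time t from the stocks, then
# advance the perception and lead-time delays.
model_step <- function(state, t, dt, cfg, ctx) {
  commuters <- project_commuters(t, cfg)
  indices <- c(light_vehicle = state[["idx_light_vehicle"]],
               bicycle = state[["idx_bicycle"]],
               walk = 1, public_transport = 1)
  shares <- mode_shares_from_perceptions(attractiveness_from_indices(indices, cfg),
                                         cfg)
  cyclists <- shares[["bicycle"]] * commuters
  vkt <- annual_lv_vkt(shares[["light_vehicle"]], commuters, cfg)

  p <- rollout_fraction(t, cfg)
  eff <- apply_policy_effects(p, cfg)

  vkt_ratio <- vkt / ctx$vkt0
  volume_ratio <- c(local = vkt_ratio * eff$volume_mult_local,
                    arterial = vkt_ratio)
  sinm <- sin_multiplier(shares[["bicycle"]], cfg$injury$sin)
  coll <- annual_collisions(cyclists, eff$local_cycle_share, volume_ratio,
                            eff$collision_rr, sinm, eff$speed_delta_local, cfg)
  sev <- severity_split(coll, ctx$speeds, cfg)
  rate <- injury_rate_per_1000(sev$fatal, sev$serious, cyclists)

  perceived <- perceived_safety_from_injuries(sev$fatal, sev$serious,
                                              ctx$safety_curve)
  perceived <- min(cfg$demand$perceived_safe_max, perceived * eff$safety_mult)

  pop_scale <- commuters / ctx$commuters0
  burden <- air_pollution_burden(t, vkt, ctx$vkt0, pop_scale, cfg)
  ghg <- ghg_co2eq(t, vkt, commuters, cfg)
  fuel <- fuel_cost(t, vkt, cfg)
  car_fatal <- cfg$injury$car_occupant_fatalities_per_bn_km * vkt / 1e9

  out <- c(
    commuters = commuters,
    share_light_vehicle = shares[["light_vehicle"]],
    share_bicycle = shares[["bicycle"]],
    share_walk = shares[["walk"]],
    share_public_transport = shares[["public_transport"]],
    cyclists = cyclists,
    lv_vkt = vkt,
    rollout = p,
    collisions = sum(coll),
    fatal = sev$fatal,
    serious = sev$serious,
    injury_rate_per_1000 = rate,
    perceived_safe = perceived,
    sin_mult = sinm,
    air_deaths = burden$deaths,
    air_hospitalisations = burden$hospitalisations,
    air_copd = burden$copd,
    air_cancers = burden$cancers,
    air_rad = burden$restricted_activity_days,
    ghg_total_t = ghg$total_t,
    ghg_per_capita_t = ghg$per_capita_t,
    fuel_cost_nzd = fuel,
    car_occupant_fatalities = car_fatal
  )

  raw <- raw_perception_indices(t, perceived, eff, cfg)
  new_state <- c(
    idx_light_vehicle = update_perceptions(state[["idx_light_vehicle"]],
                                           raw[["light_vehicle"]], dt, cfg),
    idx_bicycle = update_perceptions(state[["idx_bicycle"]],
                                     raw[["bicycle"]], dt, cfg),
    cyclists_effective = delay_step(state[["cyclists_effective"]], cyclists,
                                    cfg$phys_activity$lead_time_years, dt)
  )
  list(state = new_state, out = out)
}

#' Run one policy scenario
#'
#' Simulates the full model over the configured grid: commuting demand with
#' delayed mode perceptions, cyclist injuries with the safety-in-numbers
#' threshold and perception feedback, and the air-pollution, greenhouse-gas,
#' fuel-cost and car-occupant outcome sectors. Deterministic given the
#' configuration.
#'
#' @param config A [scenario_config()], a scenario name (`"baseline"`,
#'   `"rcn"`, `"asbl"`, `"ser"`, `"asbl_ser"`), or a path to a YAML config.
#' @param grid Optional [time_grid()] overriding the config's grid.
#' @return An object of class `cyclesim_run`: list with `scenario`, `config`,
#'   `grid` and the per-step `trajectory` tibble (one row per grid time,
#'   both endpoints included).
#' @examples
#' run <- run_scenario("baseline", grid = time_grid(1991, 2001, 0.25))
#' dplyr::last(run$trajectory$share_bicycle)
#' @export
run_scenario <- function(config = "baseline", grid = NULL) {
  cfg <- as_scenario_config(config)
  if (!is.null(grid)) {
    stopifnot(inherits(grid, "time_grid"))
    cfg$grid <- list(start_year = grid$start_year, end_year = grid$end_year,
                     dt = grid$dt)
  }
  g <- time_grid(cfg$grid$start_year, cfg$grid$end_year, cfg$grid$dt)
  ctx <- init_context(cfg)
  init <- c(idx_light_vehicle = 1, idx_bicycle = 1,
            cyclists_effective = ctx$cyclists0)
  traj <- euler_integrate(function(s, t, dt) model_step(s, t, dt, cfg, ctx),
                          g, init)
  structure(list(scenario = cfg$scenario, config = cfg, grid = g,
                 trajectory = traj),
            class = "cyclesim_run")
}

as_scenario_config <- function(config) {
  if (inherits(config, "scenario_config")) return(config)
  if (is.character(config) && length(config) == 1) {
    if (file.exists(config)) return(load_config(config))
    return(scenario_config(config))
  }
  stop("run_scenario: config must be a scenario_config, scenario name or ",
       "path to a YAML file", call. = FALSE)
}

#' @export
print.cyclesim_run <- function(x, ...) {
  last <- x$trajectory[nrow(x$trajectory), ]
  cat("<cyclesim_run>", x$scenario, "scenario,",
      x$grid$start_year, "-", x$grid$end_year, "\n")
  cat(sprintf("  %d steps (dt = %g yr); 2051 bicycle share %.3f, LV share %.3f\n",
              x$grid$n_steps, x$grid$dt,
              last$share_bicycle, last$share_light_vehicle))
  invisible(x)
}

#' Run a scenario together with its business-as-usual baseline
#'
#' Convenience wrapper running the named scenario and the baseline on the
#' same grid, with cumulative scenario-minus-baseline outcomes, monetization
#' and the benefit-cost ratio.
#'
#' @param scenario Scenario name or [scenario_config()].
#' @param grid Optional [time_grid()].
#' @param baseline Optional pre-computed baseline `cyclesim_run` (must share
#'   the grid); re-used across scenarios to save work.
#' @return An object of class `cyclesim_comparison`: `run`, `baseline`,
#'   `outcomes` (see [accumulate_outcomes()]), `monetized`, `net_benefit_nzd_m`,
#'   `bcr`.
#' @export
compare_to_baseline <- function(scenario, grid = NULL, baseline = NULL) {
  run <- run_scenario(scenario, grid = grid)
  if (is.null(baseline)) {
    base_cfg <- scenario_config("baseline")
    base_cfg$grid <- run$config$grid
    # structural/demand-side overrides carried by the scenario config must
    # also apply to its baseline for a like-for-like comparison
    for (blk in c("demand", "injury", "env", "phys_activity")) {
      base_cfg[[blk]] <- run$config[[blk]]
    }
    baseline <- run_scenario(base_cfg)
  }
  outcomes <- accumulate_outcomes(run, baseline)
  monetized <- monetize(outcomes, run$config)
  bc <- benefit_cost_ratio(monetized, infrastructure_cost(run$config))
  structure(list(run = run, baseline = baseline, outcomes = outcomes,
                 monetized = monetized,
                 net_benefit_nzd_m = bc$net_benefit, bcr = bc$bcr),
            class = "cyclesim_comparison")
}

#' @export
print.cyclesim_comparison <- function(x, ...) {
  cat("<cyclesim_comparison>", x$run$scenario, "vs baseline\n")
  cat(sprintf("  net benefit: %.0f $NZ million; BCR: %.1f\n",
              x$net_benefit_nzd_m, x$bcr))
  print(x$monetized)
  invisible(x)
}
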