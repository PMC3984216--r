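# Cyclist fatal/serious injury model: thresholded safety-in-numbers,
# vehicle-volume nonlinearity per road class, speed-severity curves and the
# injury-counts -> sense-of-safety feedback.
#
# Five steps per model time: (1) allocate cyclists and vehicle volume to
# local vs arterial roads; (2) baseline per-cyclist collision rates carry the
# underreporting adjustment for serious injuries; (3) annual cyclist-car
# collisions scale with cyclist exposure, a square-root nonlinearity in
# vehicle volume, policy relative risks and the safety-in-numbers multiplier;
# (4) collisions split into fatal and serious outcomes via speed-severity
# curves; (5) a combined rate per 1,000 cyclists closes the perception loop.

#' Safety-in-numbers multiplier on per-cyclist collision risk
#'
#' No effect at or below the threshold bicycle mode share (2.5% by default);
#' above it, per-cyclist risk scales as `(share / threshold) ^ exponent` with
#' the default exponent -0.3 — half the classic ecological power function on
#' per-cyclist risk — giving a multiplier continuous at the threshold. A
#' structural alternative (`pure_jacobsen = TRUE`) applies the full -0.6
#' power relative to a reference share with no threshold, for hypothesis
#' testing against historical data.
#'
#' @param bike_share Bicycle mode share in `[0, 1]`.
#' @param sin List with `enabled`, `threshold_share`, `exponent`,
#'   `pure_jacobsen`, `jacobsen_exponent`, `jacobsen_reference_share`
#'   (see [scenario_config()]`$injury$sin`).
#' @return Dimensionless multiplier in `(0, 1]` (thresholded variant), or the
#'   unbounded pure power law for the no-threshold variant.
#' @examples
#' sin <- scenario_config()$injury$sin
#' sin_multiplier(0.02, sin)  # 1: below threshold
#' sin_multiplier(0.10, sin)  # (4)^-0.3 ~= 0.66
#' @export
sin_multiplier <- function(bike_share, sin) {
  stopifnot(all(bike_share >= 0), all(bike_share <= 1))
  if (sin$threshold_share <= 0) {
    stop("sin_multiplier: threshold_share must be positive", call. = FALSE)
  }
  if (isTRUE(sin$pure_jacobsen)) {
    return((pmax(bike_share, 1e-6) / sin$jacobsen_reference_share)^
             sin$jacobsen_exponent)
  }
  if (!isTRUE(sin$enabled)) return(rep(1, length(bike_share)))
  out <- rep(1, length(bike_share))
  above <- bike_share > sin$threshold_share
  out[above] <- (bike_share[above] / sin$threshold_share)^sin$exponent
  out
}

#' Annual cyclist-car collisions per road class
#'
#' Per class: `baseline_rate * cyclist exposure * (vehicle volume relative to
#' baseline) ^ exponent * policy relative risk * safety-in-numbers multiplier
#' * speed-effect multiplier`. The square-root default for the volume
#' exponent reflects the sublinear crash-prediction relationship between
#' traffic volume and cyclist collisions. Mean-speed changes on local streets
#' act through an exponential collision multiplier (`0.4 ^ (reduction/10)`:
#' a 10 km/h reduction removes 60% of collisions).
#'
#' @param cyclists Total bicycle commuters.
#' @param local_cycle_share Fraction of cyclist distance on local roads.
#' @param volume_ratio Named vector (`local`, `arterial`): current vehicle
#'   volume on the class divided by its 1991 baseline volume.
#' @param policy_rr Named vector (`local`, `arterial`) of region-level
#'   collision relative risks from infrastructure.
#' @param sinm Safety-in-numbers multiplier (see [sin_multiplier()]).
#' @param speed_delta_local Change in local mean speed (km/h, <= 0 under
#'   traffic calming).
#' @param cfg A [scenario_config()].
#' @return Named vector (`local`, `arterial`) of collisions per year.
#' @export
annual_collisions <- function(cyclists, local_cycle_share, volume_ratio,
                              policy_rr, sinm, speed_delta_local, cfg) {
  i <- cfg$injury
  stopifnot(cyclists >= 0, all(volume_ratio >= 0))
  exposure <- cyclists * c(local = local_cycle_share,
                           arterial = 1 - local_cycle_share)
  vol_exp <- c(local = i$volume_exponent_local,
               arterial = i$volume_exponent_arterial)
  speed_mult <- c(
    local = i$speed_collision_mult_per_10kmh^(max(0, -speed_delta_local) / 10),
    arterial = 1
  )
  i$baseline_collision_rate * exposure *
    volume_ratio[c("local", "arterial")]^vol_exp *
    policy_rr[c("local", "arterial")] * sinm * speed_mult
}

#' Speed-severity curves
#'
#' Logistic-shaped lookup mapping mean vehicle speed (km/h) to the
#' conditional probability of a fatal or serious outcome given a collision.
#' The curves are monotone nondecreasing in speed and clamp outside
#' 0--120 km/h.
#'
#' @param outcome `"fatal"` or `"serious"`.
#' @param cfg A [scenario_config()].
#' @return A [lookup_fn()] over speed.
#' @export
severity_curve <- function(outcome = c("fatal", "serious"), cfg) {
  outcome <- match.arg(outcome)
  p <- cfg$injury$severity_curves[[outcome]]
  v <- seq(0, 120, by = 2.5)
  lookup_fn(v, p$scale * stats::plogis((v - p$location) / p$slope))
}

#' Split collisions into fatal and serious injuries
#'
#' Applies the speed-severity curves at each road class's mean speed, with
#' the serious-injury severity scale (fitted in calibration) and the known
#' underreporting adjustment for serious bicycling injuries. Dynamic speed
#' reductions under traffic calming act on collision numbers (see
#' [annual_collisions()]), so the class mean speeds passed here are the
#' calibrated severity operating points.
#'
#' @param collisions Named vector (`local`, `arterial`) of annual collisions.
#' @param speeds Named vector (`local`, `arterial`) of mean speeds (km/h).
#' @param cfg A [scenario_config()].
#' @return List with annual `fatal` and `serious` counts (underreporting
#'   adjusted).
#' @export
severity_split <- function(collisions, speeds, cfg) {
  stopifnot(all(speeds > 0))
  if (any(speeds > 120)) {
    warning("severity_split: speed above lookup range; clamped to 120 km/h")
  }
  fcurve <- severity_curve("fatal", cfg)
  scurve <- severity_curve("serious", cfg)
  cls <- c("local", "arterial")
  pf <- lookup_eval(fcurve, speeds[cls])
  ps <- lookup_eval(scurve, speeds[cls])
  list(
    fatal = sum(collisions[cls] * pf),
    serious = sum(collisions[cls] * ps * cfg$injury$severity_scale *
                    cfg$injury$underreporting_multiplier)
  )
}

#' Combined fatal and serious injury rate per 1,000 cyclists
#'
#' @param fatal,serious Annual counts.
#' @param cyclists Number of bicycle commuters.
#' @return Rate per 1,000 cyclists; `NA_real_` when there are no cyclists
#'   (undefined rate, not a division error).
#' @examples
#' injury_rate_per_1000(8, 192, 20000) # 10
#' @export
injury_rate_per_1000 <- function(fatal, serious, cyclists) {
  ifelse(cyclists > 0, 1000 * (fatal + serious) / cyclists, NA_real_)
}

#' Build the injury-counts -> sense-of-safety curve
#'
#' Monotone nonincreasing lookup giving the fraction of the population that
#' considers bicycling "always or mostly" safe as a function of the annual
#' fatal + serious count. The shape is a power law in counts relative to the
#' calibration anchor: baseline-era counts map to the surveyed 19%, zero
#' injuries map to the curve maximum.
#'
#' @param baseline_counts Annual fatal + serious injuries in the calibration
#'   era (anchor).
#' @param cfg A [scenario_config()].
#' @return A [lookup_fn()] over annual injury counts.
#' @export
build_safety_curve <- function(baseline_counts, cfg) {
  d <- cfg$demand
  stopifnot(baseline_counts > 0)
  rel <- c(0.02, 0.05, 0.1, 0.2, 0.35, 0.5, 0.75, 1, 1.5, 2, 3, 5, 8, 12,
           20, 40)
  y <- pmin(d$perceived_safe_max,
            d$perceived_safe_baseline * rel^(-d$injury_feedback_gamma))
  lookup_fn(c(0, rel * baseline_counts), c(d$perceived_safe_max, y))
}

#' Perceived safety of bicycling from injury counts
#'
#' Evaluates the calibrated sense-of-safety curve at the current annual
#' fatal + serious count: monotone nonincreasing in injuries, equal to the
#' survey anchor (19% by default) at baseline-era counts and to the curve
#' maximum at zero injuries.
#'
#' @param fatal,serious Annual counts (>= 0).
#' @param curve Lookup from [build_safety_curve()].
#' @return Fraction of the population considering bicycling always or mostly
#'   safe.
#' @export
perceived_safety_from_injuries <- function(fatal, serious, curve) {
  stopifnot(all(fatal >= 0), all(serious >= 0))
  lookup_eval(curve, fatal + serious)
}

#' Calibrate the injury model to a historical series
#'
#' Fits the baseline collision rate and the serious-injury severity scale to
#' observed annual fatal and serious counts, given the exposure path (cyclist
#' numbers and relative vehicle volume) implied by the model run over the
#' same years. Both parameters enter linearly, so the least-squares/Poisson
#' scale solutions are ratio-of-sums in closed form: the collision rate from
#' the fatal series, the severity scale from the serious series given the
#' fitted rate.
#'
#' @param history A `synthetic_history` (see [gen_history()]) or a data frame
#'   with columns `year`, `fatal_obs`, `serious_obs`.
#' @param cfg A [scenario_config()]; its collision rate and severity scale
#'   are treated as unknowns.
#' @return List with `baseline_collision_rate`, `severity_scale`, and the
#'   fitted annual `predicted` tibble.
#' @export
calibrate_injury <- function(history, cfg) {
  obs <- if (inherits(history, "synthetic_history")) history$observations else history
  stopifnot(all(c("year", "fatal_obs", "serious_obs") %in% names(obs)))
  # unit-rate model: per-year fatal and serious counts with
  # baseline_collision_rate = 1 and severity_scale = 1
  unit <- injury_expectation_path(cfg, years = obs$year,
                                  baseline_collision_rate = 1,
                                  severity_scale = 1)
  rate_hat <- sum(obs$fatal_obs) / sum(unit$fatal)
  sev_hat <- sum(obs$serious_obs) / (rate_hat * sum(unit$serious))
  list(
    baseline_collision_rate = rate_hat,
    severity_scale = sev_hat,
    predicted = tibble::tibble(
      year = obs$year,
      fatal = rate_hat * unit$fatal,
      serious = rate_hat * sev_hat * unit$serious
    )
  )
}

# Expected annual fatal/serious paths over `years` for given injury
# parameters, holding the demand-side trajectory at the deterministic
# baseline run (whose share path is invariant to the injury scale because
# the sense-of-safety feedback is anchored to the run's own baseline-era
# counts).
injury_expectation_path <- function(cfg, years,
                                    baseline_collision_rate = NULL,
                                    severity_scale = NULL) {
  cfg2 <- cfg
  if (!is.null(baseline_collision_rate)) {
    cfg2$injury$baseline_collision_rate <- baseline_collision_rate
  }
  if (!is.null(severity_scale)) cfg2$injury$severity_scale <- severity_scale
  run <- run_scenario(cfg2)
  traj <- run$trajectory[run$trajectory$year %in% years, ]
  tibble::tibble(year = traj$year, fatal = traj$fatal, serious = traj$serious)
}
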