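cfg <- scenario_config()

test_that("safety-in-numbers multiplier is thresholded and continuous", {
  sin <- cfg$injury$sin
  expect_equal(sin_multiplier(0.02, sin), 1)
  expect_equal(sin_multiplier(0.025, sin), 1)           # continuity at threshold
  expect_equal(sin_multiplier(0.025 + 1e-9, sin), 1, tolerance = 1e-6)
  expect_equal(sin_multiplier(0.10, sin), 4^-0.3, tolerance = 1e-12)
  expect_true(all(sin_multiplier(seq(0, 1, 0.01), sin) <= 1))
  off <- sin; off$enabled <- FALSE
  expect_equal(sin_multiplier(0.2, off), 1)
  pj <- sin; pj$pure_jacobsen <- TRUE
  expect_equal(sin_multiplier(0.02, pj), 1)             # at the reference share
  expect_equal(sin_multiplier(0.01, pj), 2^0.6, tolerance = 1e-12)
  bad <- sin; bad$threshold_share <- 0
  expect_error(sin_multiplier(0.1, bad), "threshold")
})

test_that("annual collisions scale with exposure, volume power law and policies", {
  unit <- c(local = 1, arterial = 1)
  expect_equal(unname(annual_collisions(0, 0.5, unit, unit, 1, 0, cfg)), c(0, 0))
  # calibration identity: baseline inputs reproduce the baseline rate
  base <- annual_collisions(8000, 0.5, unit, unit, 1, 0, cfg)
  expect_equal(sum(base), cfg$injury$baseline_collision_rate * 8000)
  # vehicle volume x4 with exponent 0.5 doubles collisions
  quad <- annual_collisions(8000, 0.5, c(local = 4, arterial = 4), unit, 1, 0, cfg)
  expect_equal(unname(quad), unname(2 * base))
  # a 10 km/h local speed reduction removes 60% of local collisions
  calmed <- annual_collisions(8000, 0.5, unit, unit, 1, -10, cfg)
  expect_equal(calmed[["local"]], 0.4 * base[["local"]])
  expect_equal(calmed[["arterial"]], base[["arterial"]])
})

test_that("severity split is monotone in speed and linear in collisions", {
  none <- severity_split(c(local = 0, arterial = 0),
                         c(local = 40, arterial = 55), cfg)
  expect_equal(none$fatal + none$serious, 0)
  slow <- severity_split(c(local = 100, arterial = 100),
                         c(local = 30, arterial = 30), cfg)
  fast <- severity_split(c(local = 100, arterial = 100),
                         c(local = 50, arterial = 50), cfg)
  expect_gte(fast$fatal, slow$fatal)
  expect_gte(fast$serious, slow$serious)
  expect_warning(severity_split(c(local = 1, arterial = 1),
                                c(local = 40, arterial = 130), cfg),
                 "clamped")
})

test_that("the default calibration reproduces the baseline-era injury level", {
  tr <- cached_run("baseline")$trajectory
  expect_equal(tr$fatal[1], 1.5, tolerance = 0.02)
  expect_equal(tr$serious[1], 33, tolerance = 0.02)
  expect_equal(tr$injury_rate_per_1000[1],
               1000 * (tr$fatal[1] + tr$serious[1]) / 8000)
})

test_that("injury rate per 1,000 handles its edge cases", {
  expect_equal(injury_rate_per_1000(8, 192, 20000), 10)
  expect_equal(injury_rate_per_1000(8, 192, 40000), 5)
  expect_true(is.na(injury_rate_per_1000(1, 1, 0)))
})

test_that("sense of safety is anchored at 19% and monotone in injuries", {
  curve <- build_safety_curve(34.5, cfg)
  expect_equal(perceived_safety_from_injuries(1.5, 33, curve), 0.19,
               tolerance = 1e-9)
  expect_equal(perceived_safety_from_injuries(0, 0, curve),
               cfg$demand$perceived_safe_max)
  expect_lt(perceived_safety_from_injuries(15, 330, curve), 0.19)
  counts <- seq(0, 600, by = 5)
  s <- perceived_safety_from_injuries(counts, 0, curve)
  expect_true(all(diff(s) <= 1e-12))
  expect_true(all(s > 0 & s <= 1))
})

test_that("the balancing injury loop damps a perception pulse", {
  grid <- time_grid(1991, 2031, 0.25)
  base_cfg <- scenario_config("baseline", list(grid = list(end_year = 2031)))
  ctx <- cyclesim:::init_context(base_cfg)
  run_from <- function(bike_idx0) {
    euler_integrate(function(s, t, dt) {
      cyclesim:::model_step(s, t, dt, base_cfg, ctx)
    }, grid, c(idx_light_vehicle = 1, idx_bicycle = bike_idx0,
               cyclists_effective = ctx$cyclists0))
  }
  ref <- run_from(1)
  pulsed <- run_from(1.6)  # exogenous upward perception pulse
  gap <- abs(pulsed$share_bicycle - ref$share_bicycle)
  expect_gt(gap[1], 0.005)
  # the pulse decays by an order of magnitude within the run, no divergence
  expect_lt(dplyr::last(gap), gap[1] / 10)
  expect_true(all(is.finite(pulsed$share_bicycle)))
})
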