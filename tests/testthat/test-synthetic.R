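test_that("zero-noise history equals the deterministic baseline run", {
  cfg <- scenario_config()
  h <- gen_history(seed = 1, cfg, noise = FALSE)
  expect_equal(h$observations$fatal_obs, h$truth$fatal)
  expect_equal(h$observations$serious_obs, h$truth$serious)
  census <- !is.na(h$observations$bike_share_obs)
  expect_equal(h$observations$bike_share_obs[census],
               h$truth$bike_share[census])
  expect_equal(h$observations$year, 1991:2012)
  # and it matches the model run directly
  run <- run_scenario(scenario_config("baseline",
                                      list(grid = list(end_year = 2012))))
  gof <- goodness_of_fit(run, h)
  expect_equal(gof$injury_mape, 0)
  expect_equal(gof$share_mape, 0)
})

test_that("histories are reproducible from the seed and plausibly scaled", {
  cfg <- scenario_config()
  h1 <- gen_history(seed = 42, cfg)
  h2 <- gen_history(seed = 42, cfg)
  expect_identical(h1$observations, h2$observations)
  h3 <- gen_history(seed = 43, cfg)
  expect_false(identical(h1$observations$fatal_obs, h3$observations$fatal_obs))
  # mean census share in the documented band around ~1-2%
  shares <- h1$observations$bike_share_obs
  expect_gt(mean(shares, na.rm = TRUE), 0.005)
  expect_lt(mean(shares, na.rm = TRUE), 0.025)
  expect_true(all(h1$observations$fatal_obs >= 0))
  expect_true(all(h1$observations$serious_obs == round(h1$observations$serious_obs)))
})

test_that("goodness of fit is a mean absolute percentage error", {
  cfg <- scenario_config()
  h <- gen_history(seed = 5, cfg, noise = FALSE)
  run <- run_scenario(scenario_config("baseline",
                                      list(grid = list(end_year = 2012))))
  # inflate observations by 10%: MAPE of the unchanged run is 10%
  h$observations$fatal_obs <- h$observations$fatal_obs / 1.1
  h$observations$serious_obs <- h$observations$serious_obs / 1.1
  expect_equal(goodness_of_fit(run, h)$injury_mape, 10, tolerance = 1e-6)
  empty <- h
  empty$observations$year <- empty$observations$year + 500
  expect_error(goodness_of_fit(run, empty), "overlap")
})

test_that("identical injury variants tie in the hypothesis test", {
  cfg <- scenario_config()
  cfg$injury$sin$exponent <- 0
  cfg$injury$sin$jacobsen_exponent <- 0
  h <- gen_history(seed = 3, cfg)
  res <- sin_hypothesis_test(h, cfg)
  expect_equal(res$fit_with_threshold_sin, res$fit_with_pure_jacobsen,
               tolerance = 1e-9)
  expect_identical(res$preferred_model, "threshold")
})

test_that("calibration recovers generating injury parameters from clean data", {
  gen <- scenario_config("baseline", list(injury = list(
    baseline_collision_rate = 0.042, severity_scale = 0.31
  )))
  h <- gen_history(seed = 1, gen, noise = FALSE)
  fit <- calibrate_injury(h, scenario_config("baseline"))
  expect_equal(fit$baseline_collision_rate, 0.042, tolerance = 0.01)
  expect_equal(fit$severity_scale, 0.31, tolerance = 0.01)
  expect_equal(fit$predicted$fatal, h$observations$fatal_obs, tolerance = 0.01)
})
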