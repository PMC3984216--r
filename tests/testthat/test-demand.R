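cfg <- scenario_config()

test_that("commuter projection grows 40% over the study period", {
  expect_equal(project_commuters(1991, cfg), 400000)
  expect_equal(project_commuters(2051, cfg), 560000, tolerance = 1e-3)
  expect_equal(project_commuters(2021, cfg), 400000 * 1.4^0.5, tolerance = 1e-9)
  # exponential: constant annual growth rate
  yrs <- 1991:2051
  g <- diff(log(project_commuters(yrs, cfg)))
  expect_equal(max(g) - min(g), 0, tolerance = 1e-12)
})

test_that("relative-utility shares reproduce the baseline and respond to indices", {
  ones <- c(light_vehicle = 1, bicycle = 1, walk = 1, public_transport = 1)
  expect_equal(mode_shares_from_perceptions(ones, cfg),
               c(light_vehicle = 0.85, bicycle = 0.02, walk = 0.055,
                 public_transport = 0.075))
  doubled <- ones; doubled[["bicycle"]] <- 2
  s <- mode_shares_from_perceptions(doubled, cfg)
  expect_equal(s[["bicycle"]], 0.04 / 1.02, tolerance = 1e-12)
  expect_equal(sum(s), 1)
  # distance cap binds and the excess is renormalized
  extreme <- ones; extreme[["bicycle"]] <- 1e6
  s2 <- mode_shares_from_perceptions(extreme, cfg)
  expect_equal(s2[["bicycle"]], cfg$demand$cyclable_fraction)
  expect_equal(sum(s2), 1)
  expect_error(mode_shares_from_perceptions(ones * 0, cfg), "degenerate")
})

test_that("light-vehicle kilometres follow the occupancy-adjusted formula", {
  cfg400 <- scenario_config("baseline", list(demand = list(
    annual_commute_trips = 400, median_lv_commute_km = 10, lv_occupancy = 1.25
  )))
  expect_equal(annual_lv_vkt(0.85, 400000, cfg400), 1.088e9)
  expect_equal(annual_lv_vkt(0, 400000, cfg400), 0)
  half <- scenario_config("baseline", list(demand = list(
    annual_commute_trips = 400, median_lv_commute_km = 10, lv_occupancy = 2.5
  )))
  expect_equal(annual_lv_vkt(0.85, 400000, half),
               annual_lv_vkt(0.85, 400000, cfg400) / 2)
  bad <- cfg400; bad$demand$lv_occupancy <- 0
  expect_error(annual_lv_vkt(0.85, 400000, bad), "occupancy")
})

test_that("shares sum to one at every step of every scenario", {
  for (s in c("baseline", "rcn", "asbl", "ser", "asbl_ser")) {
    tr <- cached_run(s)$trajectory
    total <- tr$share_light_vehicle + tr$share_bicycle + tr$share_walk +
      tr$share_public_transport
    expect_equal(total, rep(1, nrow(tr)), tolerance = 1e-9)
    expect_true(all(tr$share_bicycle <= cfg$demand$cyclable_fraction + 1e-12))
    expect_true(all(tr$share_walk <= cfg$demand$walkable_fraction + 1e-12))
  }
})

test_that("baseline bicycle share oscillates near its low equilibrium", {
  tr <- cached_run("baseline")$trajectory
  expect_true(all(tr$share_bicycle >= 0.005 & tr$share_bicycle <= 0.03))
})

test_that("raising only the bicycle perception never lowers the bicycle share", {
  ones <- c(light_vehicle = 1, bicycle = 1, walk = 1, public_transport = 1)
  mult <- seq(1, 30, length.out = 40)
  shares <- vapply(mult, function(m) {
    a <- ones; a[["bicycle"]] <- m
    mode_shares_from_perceptions(a, cfg)[["bicycle"]]
  }, numeric(1))
  expect_true(all(diff(shares) >= -1e-12))
})

test_that("perception smoothing uses the one-year preference delay", {
  sm <- update_perceptions(c(bicycle = 1), c(bicycle = 1.5), dt = 0.25, cfg)
  expect_equal(sm[["bicycle"]], 1 + 0.5 * 0.25 / 1)
  expect_error(update_perceptions(c(bicycle = 1), c(bicycle = -1), 0.25, cfg),
               "positive")
})
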