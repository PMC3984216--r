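test_that("rollout fractions respect scenario windows", {
  expect_equal(rollout_fraction(c(1991, 2020, 2051), scenario_config("baseline")),
               c(0, 0, 0))
  expect_gte(rollout_fraction(2040, scenario_config("rcn")), 0.99)
  expect_lt(rollout_fraction(2026, scenario_config("asbl")), 0.5)
  expect_equal(rollout_fraction(2011, scenario_config("asbl_ser")), 0)
})

test_that("region-wide collision relative risks combine coverage and treatment", {
  expect_equal(network_collision_rr(1, 1, 0.72, 0.8, 0.5), 0.76)
  expect_equal(network_collision_rr(1, 0.46, 0.9), 0.954)
  expect_equal(network_collision_rr(0, 1, 0.5), 1)
  # with component RR <= 1 the region RR is <= 1 and nonincreasing in p
  p <- seq(0, 1, by = 0.05)
  rr <- network_collision_rr(p, 0.8, 0.7, 0.9, 0.5)
  expect_true(all(diff(rr) <= 0) && all(rr <= 1))
})

test_that("policy effects scale with rollout and hit the published ceilings", {
  ser <- scenario_config("ser")
  e0 <- apply_policy_effects(0, ser)
  expect_equal(e0$commute_mult, 1)
  expect_equal(e0$speed_delta_local, 0)
  expect_equal(unname(e0$collision_rr), c(1, 1))
  e1 <- apply_policy_effects(1, ser)
  expect_equal(e1$speed_delta_local, -15)
  expect_equal(e1$volume_mult_local, 0.75)
  expect_equal(e1$local_cycle_share, 0.70)
  expect_equal(e1$lv_convenience_mult, 0.70)
  expect_equal(e1$safety_mult, 1.10)

  rcn <- apply_policy_effects(1, scenario_config("rcn"))
  expect_equal(rcn$collision_rr[["arterial"]], 0.954)
  # on-road lanes 3%/10% over 46% of arterials, off-road 2% per doubling of
  # km/100k (10 -> 25)
  expect_equal(rcn$commute_mult,
               (1 + 0.03 * 10 * 0.46) * (1 + 0.02 * log2(2.5)),
               tolerance = 1e-12)

  asbl <- apply_policy_effects(1, scenario_config("asbl"))
  expect_equal(asbl$collision_rr[["arterial"]], 1 - (1 - 0.76))
  expect_equal(asbl$safety_mult, 1.6)
  expect_equal(asbl$commute_mult, 1.4)
})

test_that("the combined scenario composes ASBL and SER effects", {
  for (p in c(0.2, 0.6, 1)) {
    both <- apply_policy_effects(p, scenario_config("asbl_ser"))
    a <- apply_policy_effects(p, scenario_config("asbl"))
    s <- apply_policy_effects(p, scenario_config("ser"))
    expect_equal(both$safety_mult, a$safety_mult * s$safety_mult)
    expect_equal(both$commute_mult, a$commute_mult * s$commute_mult)
    expect_equal(both$lv_convenience_mult, s$lv_convenience_mult)
    expect_equal(both$collision_rr[["arterial"]], a$collision_rr[["arterial"]])
    expect_equal(both$speed_delta_local, s$speed_delta_local)
    expect_equal(both$local_cycle_share, s$local_cycle_share)
  }
})

test_that("policy multipliers are continuous and monotone in rollout", {
  p <- seq(0, 1, by = 0.02)
  for (scen in c("rcn", "asbl", "ser", "asbl_ser")) {
    cfg <- scenario_config(scen)
    eff <- lapply(p, apply_policy_effects, cfg = cfg)
    safety <- vapply(eff, `[[`, numeric(1), "safety_mult")
    rr <- vapply(eff, function(e) e$collision_rr[["arterial"]], numeric(1))
    expect_true(all(diff(safety) >= 0))
    expect_true(all(diff(rr) <= 1e-12))
    expect_true(all(abs(diff(safety)) < 0.05)) # no jumps
  }
})

test_that("infrastructure costs follow the scenario", {
  expect_equal(infrastructure_cost(scenario_config("baseline")), 0)
  expect_equal(infrastructure_cost(scenario_config("rcn")), 45)
  expect_equal(infrastructure_cost(scenario_config("asbl_ser")), 630)
})
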