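cfg <- scenario_config()

test_that("accumulation integrates scenario-minus-baseline differences", {
  base <- cached_run("baseline")
  self <- accumulate_outcomes(base, base)
  expect_true(all(self$value == 0))
  # a constant difference of 10 deaths/yr over 2012-2051 accumulates to 390
  bumped <- base
  bumped$trajectory$fatal <- base$trajectory$fatal + 10
  acc <- accumulate_outcomes(bumped, base)
  expect_equal(acc$value[acc$category == "cyclist_fatalities"], 390)
  # sign convention: fewer kilometres than baseline -> negative entry
  less <- base
  less$trajectory$lv_vkt <- base$trajectory$lv_vkt - 1e8
  acc2 <- accumulate_outcomes(less, base)
  expect_equal(acc2$value[acc2$category == "lvkt_billion_km"], -0.1 * 39)
  short <- run_scenario("baseline", grid = time_grid(1991, 2041, 0.25))
  expect_error(accumulate_outcomes(short, base), "grids differ")
})

test_that("monetization applies the published unit values exactly", {
  mon <- function(category, value) {
    out <- monetize(tibble::tibble(category = category, value = value), cfg)
    out$value_nzd_m
  }
  expect_equal(mon("cyclist_fatalities", 200), 620)
  expect_equal(mon("cyclist_serious_injuries", 4000), 1300)
  expect_equal(mon("air_mortality", -80), -60)
  expect_equal(mon("air_copd", 10), 0.75)
  expect_equal(mon("car_occupant_fatalities", -170), -527)
  expect_equal(mon("pa_mortality", -4000), -12400)
  expect_equal(mon("ghg_megatons", 13), 520)
  expect_equal(mon("restricted_activity_days", -12500), -1.225)
  expect_equal(mon("cyclist_fatalities", 0), 0)
  expect_error(mon("weregild", 1), "no unit value")
})

test_that("monetization is linear", {
  a <- tibble::tibble(category = c("cyclist_fatalities", "ghg_megatons"),
                      value = c(120, -4))
  b <- tibble::tibble(category = a$category, value = c(80, -9))
  ab <- tibble::tibble(category = a$category, value = a$value + b$value)
  expect_equal(monetize(ab, cfg)$value_nzd_m,
               monetize(a, cfg)$value_nzd_m + monetize(b, cfg)$value_nzd_m)
})

test_that("net benefit and BCR follow their definitions", {
  mon <- tibble::tibble(category = c("cyclist_fatalities", "fuel_nzd_m"),
                        value = c(0, 0), value_nzd_m = c(210, -840))
  bc <- benefit_cost_ratio(mon, 630)
  expect_equal(bc$net_benefit, 630)
  expect_equal(bc$bcr, 1)
  zero <- tibble::tibble(category = "fuel_nzd_m", value = 0, value_nzd_m = 0)
  expect_equal(benefit_cost_ratio(zero, 0)$bcr, 0)
  nonzero <- tibble::tibble(category = "fuel_nzd_m", value = 0, value_nzd_m = -5)
  expect_true(is.na(benefit_cost_ratio(nonzero, 0)$bcr))
})

test_that("cumulative greenhouse-gas savings rank the scenarios as published", {
  ghg <- vapply(c("rcn", "asbl", "ser", "asbl_ser"), function(s) {
    -outcome_value(cached_comparison(s), "ghg_megatons")
  }, numeric(1))
  expect_true(ghg[["rcn"]] < ghg[["asbl"]])
  expect_true(ghg[["asbl"]] < ghg[["ser"]])
  expect_true(ghg[["ser"]] < ghg[["asbl_ser"]])
})

test_that("the scenario summary table carries counts, money and headline rows", {
  grid <- time_grid(1991, 2051, 0.5)
  tab <- scenario_summary(c("rcn", "ser"), grid = grid)
  expect_setequal(unique(tab$scenario), c("rcn", "ser"))
  expect_true(all(c("cyclist_fatalities", "bcr", "cycling_share_2051") %in%
                    tab$category))
  bcr <- tab$value[tab$category == "bcr"]
  expect_length(bcr, 2)
  expect_true(all(is.finite(bcr)))
})
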