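test_that("degenerate bounds collapse best/worst/primary to the same run", {
  cfg <- scenario_config("ser")
  cfg$sensitivity$distributions <- lapply(cfg$sensitivity$distributions,
                                          function(d) {
                                            d$low <- d$mode
                                            d$high <- d$mode
                                            d
                                          })
  bw <- best_worst_runs(cfg, grid = time_grid(1991, 2021, 0.5))
  expect_equal(bw$best$trajectory, bw$primary$trajectory)
  expect_equal(bw$worst$trajectory, bw$primary$trajectory)
})

test_that("monte carlo ensembles are reproducible and degenerate correctly", {
  cfg <- scenario_config("rcn")
  cfg$sensitivity$distributions <- lapply(cfg$sensitivity$distributions,
                                          function(d) {
                                            d$low <- d$mode
                                            d$high <- d$mode
                                            d
                                          })
  grid <- time_grid(1991, 2031, 0.5)
  mc1 <- monte_carlo(cfg, n = 1, seed = 99, grid = grid)
  primary <- run_scenario(cfg, grid = grid)
  last <- primary$trajectory[nrow(primary$trajectory), ]
  expect_equal(mc1$final$value[mc1$final$output == "share_bicycle"],
               last$share_bicycle)
  full <- scenario_config("rcn")
  a <- monte_carlo(full, n = 8, seed = 7, grid = grid)
  b <- monte_carlo(full, n = 8, seed = 7, grid = grid)
  expect_identical(a$draws, b$draws)
  expect_identical(a$final, b$final)
  expect_error(monte_carlo(full, n = 2), "seed")
})

test_that("effect classification follows the hierarchy of uncertainty", {
  ref <- cached_run("baseline")
  expect_identical(classify_effect(ref, ref, "share_bicycle"), "within_order")
  # x12 level difference with the same monotone trend
  scaled <- ref
  scaled$trajectory$fatal <- ref$trajectory$fatal * 12
  expect_identical(classify_effect(ref, scaled, "fatal"), "order_of_magnitude")
  # growth turned into decline over the final decade
  flipped <- ref
  flipped$trajectory$fatal <- max(ref$trajectory$fatal) + 2 -
    0.5 * (ref$trajectory$year - 1991)
  expect_identical(classify_effect(ref, flipped, "fatal"), "shape_change")
})

test_that("the no-threshold power law changes the shape of injury outcomes", {
  cfg <- scenario_config("asbl_ser")
  ref <- cached_run("asbl_ser")
  pj <- cfg
  pj$injury$sin$pure_jacobsen <- TRUE
  varied <- run_scenario(pj)
  expect_identical(classify_effect(ref, varied, "fatal"), "shape_change")
  expect_identical(classify_effect(ref, varied, "serious"), "shape_change")
})

test_that("lead-time variation preserves the scenario ordering of lives saved", {
  for (lt in c(1, 5)) {
    ov <- list(phys_activity = list(lead_time_years = lt))
    b <- run_scenario(scenario_config("baseline", ov))
    pa <- function(s) {
      cmp <- compare_to_baseline(scenario_config(s, ov), baseline = b)
      -outcome_value(cmp, "pa_mortality")
    }
    expect_lt(pa("rcn"), pa("asbl_ser"))
  }
})

test_that("monte carlo envelopes separate the weakest and strongest policies", {
  m_rcn <- monte_carlo("rcn", n = 30, seed = 11)
  m_both <- monte_carlo("asbl_ser", n = 30, seed = 12)
  hi_rcn <- max(m_rcn$final$value[m_rcn$final$output == "share_bicycle"])
  lo_both <- min(m_both$final$value[m_both$final$output == "share_bicycle"])
  expect_lt(hi_rcn, lo_both)
})

test_that("triangular draws respect their bounds and mode", {
  set.seed(1)
  x <- cyclesim:::rtri(5000, 1, 2, 5)
  expect_true(all(x >= 1 & x <= 5))
  expect_equal(mean(x), (1 + 2 + 5) / 3, tolerance = 0.02)
  expect_equal(cyclesim:::rtri(4, 2, 2, 2), rep(2, 4))
})
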