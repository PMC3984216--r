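test_that("s-curve rollout is logistic, clipped and monotone", {
  curve <- rollout_curve(2012, 2050)
  expect_equal(s_curve(2031, curve), 0.5)          # symmetric about midpoint
  expect_lte(s_curve(1995, curve), 0.01)           # pre-rollout floor
  expect_gte(s_curve(2050, curve), 0.99)           # completion definition
  t <- seq(1991, 2051, by = 0.25)
  expect_true(all(diff(s_curve(t, curve)) >= 0))
  expect_true(all(s_curve(t, curve) >= 0 & s_curve(t, curve) <= 1))
  expect_error(rollout_curve(2050, 2012), "completion_year")
})

test_that("lookup functions interpolate linearly and clamp at the ends", {
  f <- lookup_fn(c(0, 1), c(0, 1))
  expect_equal(lookup_eval(f, 0.5), 0.5)
  expect_equal(lookup_eval(f, -3), 0)              # clamped below first knot
  expect_equal(lookup_eval(f, 9), 1)
  g <- lookup_fn(c(0, 2, 4), c(0, 4, 4))
  expect_equal(lookup_eval(g, 3), 4)
  # evaluation at a knot returns its y exactly
  expect_identical(lookup_eval(g, c(0, 2, 4)), c(0, 4, 4))
  expect_error(lookup_fn(c(0, 0, 1), c(1, 2, 3)), "strictly increasing")
  expect_error(lookup_fn(1, 1), "two")
})

test_that("first-order delay has the exponential step response", {
  # fixed point: constant input equal to output
  expect_equal(delay_step(0.7, 0.7, tau = 1, dt = 0.25), 0.7)
  # step 0 -> 1 integrated over one time constant reaches ~1 - exp(-1)
  step_to <- function(tau, horizon, dt = 1e-3) {
    out <- 0
    for (i in seq_len(round(horizon / dt))) out <- delay_step(out, 1, tau, dt)
    out
  }
  expect_equal(step_to(tau = 1, horizon = 1), 1 - exp(-1), tolerance = 1e-3)
  expect_equal(step_to(tau = 2, horizon = 2), 1 - exp(-1), tolerance = 1e-3)
  expect_error(delay_step(0, 1, tau = 0, dt = 0.1), "tau")
  expect_error(delay_step(0, 1, tau = 1, dt = 0), "dt")
})

test_that("euler driver records both endpoints and conserves constant systems", {
  grid <- time_grid(2000, 2010, 0.5)
  still <- euler_integrate(function(s, t, dt) list(state = s, out = NULL),
                           grid, c(stock = 42))
  expect_equal(nrow(still), grid$n_steps + 1)
  expect_equal(range(still$year), c(2000, 2010))
  expect_true(all(still$stock == 42))
  # constant inflow: Euler is exact for a linear ramp
  ramp <- euler_integrate(function(s, t, dt) {
    list(state = c(stock = s[["stock"]] + 3 * dt), out = NULL)
  }, grid, c(stock = 1))
  expect_equal(ramp$stock, 1 + 3 * (ramp$year - 2000), tolerance = 1e-12)
  expect_error(
    euler_integrate(function(s, t, dt) list(state = c(stock = NaN), out = NULL),
                    grid, c(stock = 1)),
    "non-finite value in 'stock'"
  )
})

test_that("time grid validates its invariants", {
  g <- time_grid(1991, 2051, 0.25)
  expect_equal(g$n_steps, 240L)
  expect_length(g$times, 241L)
  expect_error(time_grid(2051, 1991), "before")
  expect_error(time_grid(1991, 2051, -1), "positive")
  expect_error(time_grid(1991, 2000, 0.23), "integer number of steps")
})
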