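# Deterministic stock-flow simulation primitives: the time grid, piecewise
# linear lookups, first-order material delays, S-shaped rollout curves and a
# fixed-step Euler driver. Everything downstream is built on these.

#' Create a simulation time grid
#'
#' Defines the fixed-step integration grid used by every simulation run.
#' The defaults span 1991--2051 in quarter-year steps, the convention for
#' this class of policy model.
#'
#' @param start_year First calendar year of the run.
#' @param end_year Last calendar year of the run.
#' @param dt Step size in years. `(end_year - start_year) / dt` must be a
#'   whole number of steps.
#' @return An object of class `time_grid`: a list with `start_year`,
#'   `end_year`, `dt`, `n_steps` and the vector of step `times`.
#' @examples
#' grid <- time_grid()
#' length(grid$times) # 241 states including both endpoints
#' @export
time_grid <- function(start_year = 1991, end_year = 2051, dt = 0.25) {
  if (!is.numeric(start_year) || !is.numeric(end_year) || !is.numeric(dt)) {
    stop("time_grid: start_year, end_year and dt must be numeric", call. = FALSE)
  }
  if (start_year >= end_year) {
    stop("time_grid: start_year must be before end_year", call. = FALSE)
  }
  if (dt <= 0) stop("time_grid: dt must be positive", call. = FALSE)
  n <- (end_year - start_year) / dt
  if (abs(n - round(n)) > 1e-8) {
    stop("time_grid: (end_year - start_year) / dt must be an integer number of steps",
         call. = FALSE)
  }
  n <- as.integer(round(n))
  structure(
    list(start_year = start_year, end_year = end_year, dt = dt,
         n_steps = n, times = start_year + dt * seq.int(0L, n)),
    class = "time_grid"
  )
}

#' Piecewise-linear lookup function
#'
#' Carrier for the model's graphical (nonlinear) relationships, e.g. the
#' curve linking injury counts to the population's sense of cycling safety.
#' Evaluation clamps to the endpoint values outside the knot range rather
#' than extrapolating, which keeps behaviour bounded outside the calibrated
#' range.
#'
#' @param x,y Numeric vectors of knot coordinates; `x` strictly increasing,
#'   at least two knots.
#' @return An object of class `lookup_fn`.
#' @seealso [lookup_eval()]
#' @export
lookup_fn <- function(x, y) {
  if (length(x) < 2L || length(x) != length(y)) {
    stop("lookup_fn: need at least two (x, y) knots of equal length", call. = FALSE)
  }
  if (any(diff(x) <= 0)) {
    stop("lookup_fn: knot x values must be strictly increasing", call. = FALSE)
  }
  structure(list(x = as.numeric(x), y = as.numeric(y)), class = "lookup_fn")
}

#' Evaluate a lookup function
#'
#' Linear interpolation between knots; clamped to the first/last knot value
#' outside the knot range. Evaluation at a knot returns its y exactly.
#'
#' @param f A [lookup_fn()].
#' @param x Numeric vector of evaluation points.
#' @return Numeric vector of interpolated values.
#' @examples
#' f <- lookup_fn(c(0, 2, 4), c(0, 4, 4))
#' lookup_eval(f, 3) # 4
#' @export
lookup_eval <- function(f, x) {
  stopifnot(inherits(f, "lookup_fn"))
  stats::approx(f$x, f$y, xout = x, method = "linear", rule = 2)$y
}

#' Advance a first-order material delay
#'
#' Exponential smoothing toward `input` with time constant `tau`:
#' `out <- out + (input - out) * dt / tau`. Used for the one-year lag
#' between stated mode preference and revealed mode share and the two-year
#' lead time on physical-activity mortality benefits.
#'
#' @param current Current smoothed output value(s).
#' @param input Target signal value(s).
#' @param tau Delay time constant in years (> 0).
#' @param dt Step size in years (> 0).
#' @return Updated output value(s).
#' @export
delay_step <- function(current, input, tau, dt) {
  if (any(tau <= 0)) stop("delay_step: tau must be positive", call. = FALSE)
  if (dt <= 0) stop("delay_step: dt must be positive", call. = FALSE)
  current + (input - current) * dt / tau
}

#' S-shaped rollout curve
#'
#' Policy implementation fraction over time: a logistic, symmetric about the
#' midpoint of the rollout window, clipped so it is at most 1% of its range
#' at `start_year` and at least 99% at `completion_year`.
#'
#' @param start_year Year rollout begins.
#' @param completion_year Year rollout is essentially complete.
#' @param floor,ceiling Range of the curve (defaults 0 and 1).
#' @return An object of class `rollout_curve`.
#' @export
rollout_curve <- function(start_year = 2012, completion_year = 2050,
                          floor = 0, ceiling = 1) {
  if (completion_year <= start_year) {
    stop("rollout_curve: completion_year must be after start_year", call. = FALSE)
  }
  if (ceiling <= floor) stop("rollout_curve: ceiling must exceed floor", call. = FALSE)
  # steepness chosen so the logistic hits 1% / 99% of range at the endpoints
  mid <- (start_year + completion_year) / 2
  k <- 2 * log(99) / (completion_year - start_year)
  structure(list(start_year = start_year, completion_year = completion_year,
                 floor = floor, ceiling = ceiling, midpoint = mid, k = k),
            class = "rollout_curve")
}

#' Evaluate an S-shaped rollout curve
#'
#' @param t Year(s) at which to evaluate.
#' @param curve A [rollout_curve()].
#' @return Fraction(s) in `[floor, ceiling]`; 0% of range before
#'   `start_year` is enforced by clipping.
#' @examples
#' s_curve(2031, rollout_curve(2012, 2050)) # 0.5 at the window midpoint
#' @export
s_curve <- function(t, curve) {
  stopifnot(inherits(curve, "rollout_curve"))
  raw <- 1 / (1 + exp(-curve$k * (t - curve$midpoint)))
  raw[t <= curve$start_year] <- pmin(raw[t <= curve$start_year], 0.01)
  raw[t >= curve$completion_year] <- pmax(raw[t >= curve$completion_year], 0.99)
  curve$floor + (curve$ceiling - curve$floor) * raw
}

#' Fixed-step Euler integration driver
#'
#' Advances a model step function over a [time_grid()] and collects one
#' record per grid point (both endpoints included). The step function
#' receives `(state, t, dt)` and must return `list(state = ..., out = ...)`
#' where `out` is a named numeric vector of auxiliaries to record alongside
#' the stocks. Purely deterministic given its inputs.
#'
#' @param step_fn Function `(state, t, dt) -> list(state, out)`.
#' @param grid A [time_grid()].
#' @param init Named numeric vector: the initial stocks, valid at
#'   `grid$start_year`.
#' @return A tibble with one row per grid time: `year`, stocks and outputs.
#' @export
euler_integrate <- function(step_fn, grid, init) {
  stopifnot(inherits(grid, "time_grid"))
  state <- init
  n <- grid$n_steps + 1L
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    t <- grid$times[i]
    res <- step_fn(state, t, grid$dt)
    bad <- !is.finite(c(res$state, res$out))
    if (any(bad)) {
      nm <- names(c(res$state, res$out))[bad][1]
      stop(sprintf("euler_integrate: non-finite value in '%s' at t = %s", nm, t),
           call. = FALSE)
    }
    # record the stocks as they stand at t alongside the auxiliaries
    # computed at t; res$state is the advanced state for the next step
    rows[[i]] <- c(year = t, state, res$out)
    state <- res$state
  }
  tibble::as_tibble(do.call(rbind, rows))
}
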