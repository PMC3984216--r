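# Structural and parametric uncertainty: best/worst-case runs at the
# intervention-effect confidence limits, seeded Monte Carlo over triangular
# distributions of the most uncertain parameters, and classification of each
# variation by the hierarchy of uncertainty effects (shape change >
# order-of-magnitude change > within-order change).

rtri <- function(n, low, mode, high) {
  if (high == low) return(rep(mode, n))
  u <- stats::runif(n)
  fc <- (mode - low) / (high - low)
  ifelse(u < fc,
         low + sqrt(u * (high - low) * (mode - low)),
         high - sqrt((1 - u) * (high - low) * (high - mode)))
}

dist_table <- function(cfg, group = NULL) {
  dists <- cfg$sensitivity$distributions
  if (!is.null(group)) {
    dists <- purrr::keep(dists, function(d) d$group %in% group)
  }
  dists
}

apply_param_values <- function(cfg, dists, values) {
  for (i in seq_along(dists)) {
    cfg <- cfg_set(cfg, dists[[i]]$path, unname(values[[i]]))
  }
  validate_config(cfg)
  cfg
}

#' Best- and worst-case scenario runs
#'
#' Re-runs a scenario with every intervention-effect parameter set
#' simultaneously to its most favourable (best) or least favourable (worst)
#' published confidence limit. Structural and epidemiological uncertainties
#' (relative risk, safety-in-numbers form, lead time) are held at their point
#' estimates here; they belong to the Monte Carlo and structural tests.
#' Deterministic.
#'
#' @param scenario Scenario name or [scenario_config()].
#' @param grid Optional [time_grid()].
#' @return List of `cyclesim_run`s: `best`, `worst`, and the point-estimate
#'   `primary`.
#' @export
best_worst_runs <- function(scenario, grid = NULL) {
  cfg <- as_scenario_config(scenario)
  dists <- dist_table(cfg, group = "policy")
  bound <- function(which) {
    vals <- vapply(dists, function(d) {
      fav <- d$favourable
      if (which == "best") {
        if (fav == "low") d$low else d$high
      } else {
        if (fav == "low") d$high else d$low
      }
    }, numeric(1))
    run_scenario(apply_param_values(cfg, dists, vals), grid = grid)
  }
  list(best = bound("best"), worst = bound("worst"),
       primary = run_scenario(cfg, grid = grid))
}

#' Monte Carlo ensemble over uncertain parameters
#'
#' Draws each uncertain parameter independently from a triangular
#' distribution between its bounds with mode at the point estimate, re-runs
#' the scenario per draw, and summarizes selected outputs. Reproducible: the
#' seed is required.
#'
#' @param scenario Scenario name or [scenario_config()].
#' @param n Number of runs.
#' @param seed Integer RNG seed (no silent nondeterminism).
#' @param grid Optional [time_grid()].
#' @param outputs Trajectory columns to summarize at the final year.
#' @return An object of class `cyclesim_mc`: `draws` (tibble of sampled
#'   parameter values), `final` (tibble: draw, output, value at end year),
#'   `summary` (per output: min, q05, median, q95, max), `seed`.
#' @export
monte_carlo <- function(scenario, n = 1000, seed, grid = NULL,
                        outputs = c("share_bicycle", "fatal", "serious",
                                    "injury_rate_per_1000")) {
  stopifnot(n >= 1)
  if (missing(seed)) stop("monte_carlo: a seed is required", call. = FALSE)
  cfg <- as_scenario_config(scenario)
  dists <- dist_table(cfg)
  set.seed(seed)
  draws <- vapply(dists, function(d) rtri(n, d$low, d$mode, d$high), numeric(n))
  if (n == 1) draws <- matrix(draws, nrow = 1)
  colnames(draws) <- vapply(dists, `[[`, character(1), "path")
  final <- purrr::map_dfr(seq_len(n), function(i) {
    run <- run_scenario(apply_param_values(cfg, dists, draws[i, ]), grid = grid)
    last <- run$trajectory[nrow(run$trajectory), ]
    tibble::tibble(draw = i, output = outputs,
                   value = as.numeric(last[outputs]))
  })
  summary <- dplyr::summarise(
    dplyr::group_by(final, .data$output),
    min = min(.data$value),
    q05 = stats::quantile(.data$value, 0.05, names = FALSE),
    median = stats::median(.data$value),
    q95 = stats::quantile(.data$value, 0.95, names = FALSE),
    max = max(.data$value),
    .groups = "drop"
  )
  structure(list(scenario = cfg$scenario,
                 draws = tibble::as_tibble(draws),
                 final = final, summary = summary, seed = seed),
            class = "cyclesim_mc")
}

#' @export
print.cyclesim_mc <- function(x, ...) {
  cat("<cyclesim_mc>", x$scenario, "ensemble of", nrow(x$draws),
      "runs (seed", paste0(x$seed, ")"), "\n")
  print(x$summary)
  invisible(x)
}

# least-squares slope over the last `window` years of a series
terminal_slope <- function(year, value, window = 10) {
  keep <- year >= max(year) - window
  stats::coef(stats::lm(value[keep] ~ year[keep]))[[2]]
}

# trend class over the terminal window: growing / declining / flat, with a
# relative flatness band of +-1% of the mean level per year
trend_class <- function(year, value, window = 10, flat_band = 0.01) {
  slope <- terminal_slope(year, value, window)
  level <- mean(abs(value[year >= max(year) - window]))
  if (level == 0 || abs(slope) <= flat_band * level) return("flat")
  if (slope > 0) "growing" else "declining"
}

#' Classify the effect of a parameter variation
#'
#' The hierarchy of uncertainty effects: a variation that changes the sign
#' of the terminal-decade trend (or its monotonicity class) is a
#' `shape_change`; one that moves the final-year value by at least a factor
#' of 10 is `order_of_magnitude`; anything else is `within_order`.
#'
#' @param reference,varied `cyclesim_run`s on the same grid.
#' @param output Trajectory column to compare.
#' @param window Terminal window (years) for trend estimation.
#' @return `"shape_change"`, `"order_of_magnitude"` or `"within_order"`.
#' @export
classify_effect <- function(reference, varied, output, window = 10) {
  if (!identical(reference$grid$times, varied$grid$times)) {
    stop("classify_effect: runs are on different grids", call. = FALSE)
  }
  yr <- reference$trajectory$year
  ref <- reference$trajectory[[output]]
  var <- varied$trajectory[[output]]
  if (trend_class(yr, ref, window) != trend_class(yr, var, window)) {
    return("shape_change")
  }
  rf <- ref[length(ref)]; vf <- var[length(var)]
  if (rf != 0 && vf != 0 && (vf / rf >= 10 || vf / rf <= 0.1)) {
    return("order_of_magnitude")
  }
  if (rf == 0 && abs(vf) > 0 || vf == 0 && abs(rf) > 0) {
    return("order_of_magnitude")
  }
  "within_order"
}

#' Sensitivity report across the uncertain-parameter list
#'
#' One-at-a-time sweep: each parameter is set to its low and high bound in
#' turn, the scenario is re-run, and the effect on each output is classified
#' per [classify_effect()].
#'
#' @param scenario Scenario name or [scenario_config()].
#' @param outputs Trajectory columns to classify.
#' @param grid Optional [time_grid()].
#' @return Tibble: `parameter`, `bound`, `output`, `classification`.
#' @export
sensitivity_report <- function(scenario,
                               outputs = c("share_bicycle", "fatal",
                                           "injury_rate_per_1000"),
                               grid = NULL) {
  cfg <- as_scenario_config(scenario)
  reference <- run_scenario(cfg, grid = grid)
  dists <- dist_table(cfg)
  purrr::map_dfr(dists, function(d) {
    purrr::map_dfr(c(low = d$low, high = d$high), function(v) {
      varied <- run_scenario(cfg_set(cfg, d$path, v), grid = grid)
      tibble::tibble(output = outputs,
                     classification = vapply(outputs, function(o) {
                       classify_effect(reference, varied, o)
                     }, character(1)))
    }, .id = "bound") |>
      dplyr::mutate(parameter = d$path, .before = 1)
  })
}
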