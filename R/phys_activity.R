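# All-cause mortality savings from regular commuter cycling: relative risk
# 0.72 with a two-year first-order lead time, against a secularly declining
# stratified baseline mortality.

#' Population-weighted baseline all-cause mortality
#'
#' Stratum rates (age groups of the commuting population) decline
#' exponentially at the secular rate and are weighted by the stable stratum
#' shares.
#'
#' @param t Year(s).
#' @param cfg A [scenario_config()].
#' @return Deaths per person per year.
#' @export
baseline_mortality <- function(t, cfg) {
  p <- cfg$phys_activity
  decay <- exp(-p$secular_decline * (t - cfg$grid$start_year))
  rate0 <- sum(vapply(p$strata, function(s) s$share * s$rate_1991, numeric(1)))
  rate0 * decay
}

#' Deaths averted by additional regular commuter cycling
#'
#' `averted = effective excess cyclists * baseline mortality * (1 - RR) *
#' dose scaling`. The effective excess is the first-order-lagged (two-year
#' lead time) difference in bicycle commuters between a scenario and its
#' baseline; the relation is symmetric, so a fall in cycling produces lives
#' lost at the same lag.
#'
#' @param t Year(s).
#' @param effective_excess_cyclists Lagged excess bicycle commuters (persons;
#'   may be negative).
#' @param cfg A [scenario_config()].
#' @return Deaths per year averted (negative = lives lost).
#' @export
deaths_averted <- function(t, effective_excess_cyclists, cfg) {
  p <- cfg$phys_activity
  effective_excess_cyclists * baseline_mortality(t, cfg) *
    (1 - p$relative_risk) * p$dose_scaling
}
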