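# Shared full-grid runs, computed once per test session.
.run_cache <- new.env(parent = emptyenv())

cached_run <- function(scenario) {
  if (is.null(.run_cache[[scenario]])) {
    .run_cache[[scenario]] <- run_scenario(scenario)
  }
  .run_cache[[scenario]]
}

cached_comparison <- function(scenario) {
  key <- paste0("cmp_", scenario)
  if (is.null(.run_cache[[key]])) {
    .run_cache[[key]] <- compare_to_baseline(scenario,
                                             baseline = cached_run("baseline"))
  }
  .run_cache[[key]]
}

at_year <- function(run, yr, col) {
  tr <- run$trajectory
  tr[[col]][which.min(abs(tr$year - yr))]
}

slope_between <- function(run, from, to, col = NULL, values = NULL) {
  tr <- run$trajectory
  v <- if (is.null(values)) tr[[col]] else values
  k <- tr$year >= from & tr$year <= to
  unname(stats::coef(stats::lm(v[k] ~ tr$year[k]))[2])
}

outcome_value <- function(cmp, category) {
  cmp$outcomes$value[cmp$outcomes$category == category]
}
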