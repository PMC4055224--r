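# Shared fixtures, built once per test run and memoised.

.fixtures <- new.env(parent = emptyenv())

# A mid-sized planted-effect experiment reused by evaluation / ordering tests.
shared_growth_experiment <- function() {
  if (is.null(.fixtures$growth)) {
    cfg <- experiment_config(
      scenarios = list(growth = true_model_growth()),
      n_persons = 4000L, n_reps = 200L, seed = 101L
    )
    .fixtures$growth <- suppressWarnings(run_experiment(cfg))
  }
  .fixtures$growth
}

# A small constant-hazard toy model reaching all six states within a year,
# with one gender effect, for DES-vs-oracle checks.
toy_true_model <- function() {
  true_model(
    baseline = list(
      "LTS->W" = 0.004, "LTS->U" = 0.002, "LTS->TO" = 0.002, "LTS->D" = 0.001,
      "W->SA" = 0.003, "W->U" = 0.002, "U->W" = 0.004, "SA->W" = 0.004,
      "SA->D" = 0.002, "TO->W" = 0.003
    ),
    hazard_ratios = list("LTS->W" = c(gendermale = 0.5)),
    censor_hazard = 0
  )
}

# One covariate row at the reference pattern, with overrides.
toy_person <- function(person_id = 1L, ...) {
  schema <- covariate_schema()
  row <- tibble::as_tibble(lapply(schema, function(l) l[[1L]]))
  over <- list(...)
  for (nm in names(over)) row[[nm]] <- over[[nm]]
  dplyr::bind_cols(tibble::tibble(person_id = person_id), row)
}

# Covariate margins that put all mass on the reference levels except where
# overridden with a named probability vector.
degenerate_margins <- function(...) {
  schema <- covariate_schema()
  margins <- lapply(schema, function(l) {
    stats::setNames(c(1, rep(0, length(l) - 1L)), l)
  })
  over <- list(...)
  for (nm in names(over)) margins[[nm]] <- over[[nm]]
  margins
}

# Hand-built timeline rows (censor_day NA unless given).
toy_timeline <- function(person_id, states, starts, ends, censor_day = NA_integer_) {
  tibble::tibble(
    person_id = person_id, state = states,
    start_day = as.integer(starts), end_day = as.integer(ends),
    censor_day = as.integer(censor_day)
  )
}

# Sorted content comparison for run tibbles (ignores row order / attributes).
sort_runs <- function(x) {
  x <- dplyr::arrange(x, .data$person_id, .data$start_day)
  as.data.frame(x[, c("person_id", "state", "start_day", "end_day")])
}
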