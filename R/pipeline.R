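# End-to-end experiment: generate -> derive -> split -> fit -> predict ->
# evaluate, per scenario, under one root seed split into named substreams.

#' Experiment configuration
#'
#' @param scenarios Named list of [true_model()] objects, one generating
#'   model per scenario label (default a growth and a recession scenario;
#'   scenarios are independent synthetic cohorts, so period comparisons are
#'   not confounded by shared samples).
#' @param n_persons Persons generated per scenario.
#' @param split_fraction Training share of the random train/validation
#'   split (0.674, i.e. roughly two thirds).
#' @param seed Root seed; generation, splitting and the DES draw from
#'   separate named substreams derived from it.
#' @param n_reps Simulated DES pathways per person (paper-scale 10,000;
#'   scale down for quick runs).
#' @param lookback_days,horizon_days,lts_min_days,min_sick_spell See
#'   [generator_config()].
#' @param margins Covariate margins, see [default_covariate_margins()].
#' @param output_dir Optional directory; when given, every artifact (spells,
#'   cohort, transition counts, model coefficients, predictions, report) is
#'   written as CSV together with the configuration.
#' @return Object of class `experiment_config`.
#' @export
experiment_config <- function(scenarios = list(
                                growth = true_model_growth(),
                                recession = true_model_recession()
                              ),
                              n_persons = 20000L,
                              split_fraction = 0.674,
                              seed = 1L,
                              n_reps = 10000L,
                              lookback_days = 365L,
                              horizon_days = 365L,
                              lts_min_days = 28L,
                              min_sick_spell = 14L,
                              margins = default_covariate_margins(),
                              output_dir = NULL) {
  if (is.null(names(scenarios)) || anyDuplicated(names(scenarios)) > 0L) {
    abort("scenarios must be a uniquely named list of true_model objects")
  }
  if (split_fraction <= 0 || split_fraction >= 1) {
    abort("split_fraction must be in (0, 1)")
  }
  structure(
    list(
      scenarios = scenarios, n_persons = as.integer(n_persons),
      split_fraction = split_fraction, seed = as.integer(seed),
      n_reps = as.integer(n_reps),
      lookback_days = as.integer(lookback_days),
      horizon_days = as.integer(horizon_days),
      lts_min_days = as.integer(lts_min_days),
      min_sick_spell = as.integer(min_sick_spell),
      margins = margins, output_dir = output_dir
    ),
    class = "experiment_config"
  )
}

#' Random train/validation split
#'
#' Deterministic random partition of person ids: `round(fraction * n)` ids
#' go to training, the rest to validation.
#'
#' @param persons Vector of person ids (or tibble with `person_id`).
#' @param fraction Training share in (0, 1).
#' @param seed Integer seed.
#' @return List with `train` and `validation` id vectors.
#' @export
split_train_validation <- function(persons, fraction = 0.674, seed = 1L) {
  if (is.data.frame(persons)) persons <- persons$person_id
  n <- length(persons)
  if (n == 0L) abort("cannot split an empty person set")
  if (fraction <= 0 || fraction >= 1) abort("fraction must be in (0, 1)")
  set.seed(seed)
  n_train <- round(fraction * n)
  idx <- sample.int(n, n_train)
  list(train = persons[idx], validation = persons[-idx])
}

#' Run the full experiment
#'
#' Per scenario: generate a synthetic register cohort from the scenario's
#' true model, derive timelines and the analysis cohort, split into training
#' and validation, fit the 20 transition-specific Cox models and the six
#' logistic models on training, predict the one-year state for validation
#' persons with both the discrete event simulation and logistic regression,
#' and score everything against the null model. Counts at each filtering
#' stage are recorded. Censored-before-outcome persons keep their DES
#' predictions but are excluded from fitting and from all metrics.
#'
#' @param config An [experiment_config()].
#' @return Object of class `lts_experiment`: per-scenario artifacts plus a
#'   combined `report` tibble (see [build_report()]).
#' @export
run_experiment <- function(config) {
  stopifnot(inherits(config, "experiment_config"))
  labels <- names(config$scenarios)
  seeds <- substream_seeds(
    config$seed,
    c(t(outer(labels, c("gen", "split", "des"), paste, sep = "_")))
  )
  scenario_results <- list()
  for (label in labels) {
    scenario_results[[label]] <- run_scenario(
      label, config$scenarios[[label]], config,
      seed_gen = seeds[[paste0(label, "_gen")]],
      seed_split = seeds[[paste0(label, "_split")]],
      seed_des = seeds[[paste0(label, "_des")]]
    )
  }
  report <- purrr::map_dfr(
    scenario_results,
    function(s) mutate(s$report, scenario = s$label, .before = 1L)
  )
  importance <- purrr::map_dfr(
    scenario_results,
    function(s) mutate(s$importance, scenario = s$label, .before = 1L)
  )
  out <- structure(
    list(
      config = config, scenarios = scenario_results,
      report = report, importance = importance
    ),
    class = "lts_experiment"
  )
  if (!is.null(config$output_dir)) write_experiment(out, config$output_dir)
  out
}

run_scenario <- function(label, model, config, seed_gen, seed_split, seed_des) {
  gcfg <- generator_config(
    n_persons = config$n_persons, margins = config$margins,
    lookback_days = config$lookback_days, horizon_days = config$horizon_days,
    lts_min_days = config$lts_min_days, min_sick_spell = config$min_sick_spell,
    seed = seed_gen, n_pathway_reps = config$n_reps
  )
  covariates <- sample_covariates(gcfg)
  histories <- simulate_histories(covariates, model, gcfg)
  timeline <- derive_timeline(
    histories$spells,
    horizon = histories$total_days,
    censor = histories$censor, persons = covariates$person_id
  )
  cohort <- assemble_cohort(
    timeline, covariates,
    inclusion_window = c(config$lookback_days, config$lookback_days),
    min_days = config$lts_min_days,
    lookback_days = config$lookback_days,
    horizon_days = config$horizon_days
  )
  index <- select(cohort, "person_id", "index_day")
  marked <- mark_initial_lts(timeline, index)

  split <- split_train_validation(cohort$person_id, config$split_fraction,
    seed = seed_split
  )
  cohort_train <- filter(cohort, .data$person_id %in% split$train)
  cohort_valid <- filter(cohort, .data$person_id %in% split$validation)

  counts <- tibble(
    stage = c(
      "generated", "eligible_lts", "training", "validation",
      "train_censored_before_outcome", "valid_censored_before_outcome"
    ),
    n = c(
      nrow(covariates), nrow(cohort), nrow(cohort_train), nrow(cohort_valid),
      sum(cohort_train$outcome == "censored"),
      sum(cohort_valid$outcome == "censored")
    )
  )

  transition_counts <- count_transitions(
    semi_join(marked, tibble(person_id = split$train), by = "person_id"),
    window = tibble(
      person_id = cohort_train$person_id,
      lo = cohort_train$index_day,
      hi = cohort_train$index_day + config$horizon_days
    )
  )

  cox_set <- fit_transition_models(
    semi_join(marked, tibble(person_id = split$train), by = "person_id"),
    cohort_train,
    horizon = config$horizon_days
  )
  logit_set <- fit_outcome_logistics(cohort_train)

  pred_logistic <- predict_outcome_probabilities(logit_set, cohort_valid)
  pred_des <- predict_state_occupation(
    cox_set, cohort_valid,
    n_reps = config$n_reps, seed = seed_des, horizon = config$horizon_days
  )
  predictions <- bind_rows(pred_logistic, select(pred_des, -"n_reps"))

  report <- build_report(cohort_train, cohort_valid, predictions)
  importance <- variable_importance(cohort_train, cohort_valid, "W")

  list(
    label = label, config = gcfg, model = model,
    histories = histories, timeline = marked,
    cohort = cohort, split = split, counts = counts,
    transition_counts = transition_counts,
    cox = cox_set, logistic = logit_set,
    predictions = predictions, report = report, importance = importance
  )
}

write_experiment <- function(x, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_csv(x$report, file.path(dir, "report.csv"))
  readr::write_csv(x$importance, file.path(dir, "importance.csv"))
  for (label in names(x$scenarios)) {
    s <- x$scenarios[[label]]
    sdir <- file.path(dir, label)
    dir.create(sdir, showWarnings = FALSE, recursive = TRUE)
    write_spell_data(s$histories, sdir)
    readr::write_csv(s$cohort, file.path(sdir, "cohort.csv"))
    readr::write_csv(s$counts, file.path(sdir, "stage_counts.csv"))
    readr::write_csv(s$transition_counts, file.path(sdir, "transition_counts.csv"))
    write_transition_models(s$cox, sdir)
    readr::write_csv(tidy(s$logistic), file.path(sdir, "logistic_coefficients.csv"))
    readr::write_csv(s$predictions, file.path(sdir, "predictions.csv"))
  }
  cfg <- x$config
  cfg$scenarios <- map(cfg$scenarios, function(m) {
    list(
      baseline = map(m$baseline, as.list),
      hazard_ratios = map(m$hazard_ratios, as.list),
      censor_hazard = m$censor_hazard
    )
  })
  cfg$margins <- map(cfg$margins, as.list)
  yaml::write_yaml(unclass(cfg), file.path(dir, "config.yaml"))
  invisible(x)
}

#' @export
print.lts_experiment <- function(x, ...) {
  cat("<lts_experiment> scenarios:", paste(names(x$scenarios), collapse = ", "), "\n")
  for (label in names(x$scenarios)) {
    s <- x$scenarios[[label]]
    cat("  ", label, ": ", s$counts$n[s$counts$stage == "eligible_lts"],
      " included persons (", s$counts$n[s$counts$stage == "training"],
      " train / ", s$counts$n[s$counts$stage == "validation"], " valid)\n",
      sep = ""
    )
  }
  cat("\nValidation report:\n")
  print(x$report, n = Inf)
  invisible(x)
}
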