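# Risk sets and per-transition Cox fits.

make_marked_path <- function() {
  # index at day 0 for simplicity: LTS 0-50, W 50-366
  toy_timeline(1L, c("LTS", "W"), c(0, 50), c(50, 366))
}

toy_cohort_row <- function(person_id = 1L, index_day = 0L, outcome = "W", ...) {
  dplyr::bind_cols(
    toy_person(person_id, ...),
    tibble::tibble(index_day = index_day, outcome = outcome)
  )
}

test_that("risk sets encode sojourns, events and competing censoring", {
  tl <- make_marked_path()
  cohort <- toy_cohort_row()
  rs_w <- build_risk_sets(tl, cohort, "LTS->W")
  expect_equal(nrow(rs_w), 1L)
  expect_equal(rs_w$entry, 0L)
  expect_equal(rs_w$exit, 50L)
  expect_equal(rs_w$event, 1L)

  rs_u <- build_risk_sets(tl, cohort, "LTS->U")
  expect_equal(rs_u$event, 0L) # competing exit = censoring for this cause
  expect_equal(rs_u$exit, 50L)

  expect_error(build_risk_sets(tl, cohort, "D->W"), "legal")
})

test_that("risk-set events per edge equal the transition-count table", {
  cfg <- generator_config(400, seed = 41)
  cov <- sample_covariates(cfg)
  hist <- simulate_histories(cov, true_model_growth(), cfg)
  tl <- derive_timeline(hist$spells, hist$total_days,
    censor = hist$censor, persons = cov$person_id
  )
  cohort <- assemble_cohort(tl, cov, inclusion_window = c(365, 365))
  marked <- mark_initial_lts(tl, dplyr::select(cohort, person_id, index_day))
  counts <- count_transitions(
    marked,
    window = tibble::tibble(
      person_id = cohort$person_id,
      lo = cohort$index_day, hi = cohort$index_day + 365L
    )
  )
  for (edge in c("LTS->W", "W->SA", "U->W", "SA->TO")) {
    rs <- build_risk_sets(marked, cohort, edge)
    expect_equal(sum(rs$event), counts$n[counts$edge == edge])
  }
})

test_that("a generating hazard ratio of 2 is recovered within 3 SE", {
  margins <- degenerate_margins(gender = c(female = 0.5, male = 0.5))
  cfg <- generator_config(4000, margins = margins, seed = 42)
  model <- true_model(
    baseline = list("LTS->W" = 0.005),
    hazard_ratios = list("LTS->W" = c(gendermale = log(2))),
    censor_hazard = 0
  )
  cov <- sample_covariates(cfg)
  hist <- simulate_histories(cov, model, cfg)
  tl <- derive_timeline(hist$spells, hist$total_days, persons = cov$person_id)
  cohort <- assemble_cohort(tl, cov, inclusion_window = c(365, 365))
  marked <- mark_initial_lts(tl, dplyr::select(cohort, person_id, index_day))
  fit <- fit_transition_cox(build_risk_sets(marked, cohort, "LTS->W"))
  est <- fit$coefficients[fit$coefficients$term == "gendermale", ]
  expect_equal(nrow(est), 1L)
  expect_lt(abs(est$estimate - log(2)), 3 * est$std_error)
})

test_that("covariates without variation are dropped and flagged", {
  tl <- dplyr::bind_rows(lapply(1:30, function(i) {
    exit <- 20L + i
    toy_timeline(i, c("LTS", "W"), c(0, exit), c(exit, 366))
  }))
  cohort <- dplyr::bind_rows(lapply(1:30, function(i) toy_cohort_row(i)))
  rs <- build_risk_sets(tl, cohort, "LTS->W")
  fit <- fit_transition_cox(rs)
  expect_equal(nrow(fit$coefficients), 0L)
  expect_true("gendermale" %in% fit$dropped_terms)
})

test_that("the null-fit baseline equals the Nelson-Aalen estimator", {
  cfg <- generator_config(600,
    margins = degenerate_margins(), seed = 43
  )
  model <- true_model(
    baseline = list("LTS->W" = 0.006, "LTS->U" = 0.002),
    censor_hazard = 0
  )
  cov <- sample_covariates(cfg)
  hist <- simulate_histories(cov, model, cfg)
  tl <- derive_timeline(hist$spells, hist$total_days, persons = cov$person_id)
  cohort <- assemble_cohort(tl, cov, inclusion_window = c(365, 365))
  marked <- mark_initial_lts(tl, dplyr::select(cohort, person_id, index_day))
  rs <- build_risk_sets(marked, cohort, "LTS->W")
  fit <- fit_transition_cox(rs) # degenerate covariates -> null fit

  # independent oracle: Nelson-Aalen on the pooled sojourns
  sf <- survival::survfit(
    survival::Surv(entry, exit, event) ~ 1,
    data = rs, ctype = 1
  )
  na_inc <- diff(c(0, sf$cumhaz))[sf$n.event > 0]
  na_time <- sf$time[sf$n.event > 0]
  expect_equal(fit$basehaz$time, as.integer(na_time))
  expect_equal(fit$basehaz$increment, na_inc, tolerance = 1e-10)
})

test_that("daily increments follow the step function and hazard ratio", {
  margins <- degenerate_margins(gender = c(female = 0.5, male = 0.5))
  cfg <- generator_config(800, margins = margins, seed = 44)
  model <- true_model(
    baseline = list("LTS->W" = 0.01),
    hazard_ratios = list("LTS->W" = c(gendermale = 0.4)),
    censor_hazard = 0
  )
  cov <- sample_covariates(cfg)
  hist <- simulate_histories(cov, model, cfg)
  tl <- derive_timeline(hist$spells, hist$total_days, persons = cov$person_id)
  cohort <- assemble_cohort(tl, cov, inclusion_window = c(365, 365))
  marked <- mark_initial_lts(tl, dplyr::select(cohort, person_id, index_day))
  fit <- fit_transition_cox(build_risk_sets(marked, cohort, "LTS->W"))

  ref <- toy_person()
  male <- toy_person(gender = "male")
  beta <- fit$coefficients$estimate[fit$coefficients$term == "gendermale"]
  cum <- cumsum(fit$inc_vec)
  for (t in c(30L, 60L, 100L)) {
    # reference pattern: increment equals the baseline jump
    expect_equal(predict_daily_increment(fit, ref, t), fit$inc_vec[t + 1])
    # any pattern: equals the brute-force Lambda(t+1) - Lambda(t)
    expect_equal(
      predict_daily_increment(fit, male, t),
      (cum[t + 1] - ifelse(t > 0, cum[t], 0)) * exp(beta)
    )
  }
  last_event <- max(fit$basehaz$time)
  if (last_event < 365) {
    expect_equal(predict_daily_increment(fit, ref, last_event), 0)
  }
})

test_that("zero-event transitions error at fit and are dropped in sets", {
  tl <- dplyr::bind_rows(lapply(1:5, function(i) {
    exit <- 30L + 10L * i
    toy_timeline(i, c("LTS", "W"), c(0, exit), c(exit, 366))
  }))
  cohort <- dplyr::bind_rows(lapply(1:5, function(i) toy_cohort_row(i)))
  rs <- build_risk_sets(tl, cohort, "LTS->U")
  expect_error(fit_transition_cox(rs), "exclude")

  expect_warning(
    set <- fit_transition_models(
      tl, cohort,
      edges = dplyr::filter(lts_transitions(), edge %in% c("LTS->W", "LTS->U"))
    ),
    "dropped"
  )
  expect_equal(set$dropped_edges, "LTS->U")
  expect_named(set$models, "LTS->W")
})
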