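# Discrete event simulation and its Markov matrix-product oracle.

test_that("one-day transition probabilities follow the competing-hazard law", {
  ref <- toy_person()
  zero <- true_model(baseline = list(), censor_hazard = 0)
  p0 <- daily_transition_probs(zero, "LTS", ref, t = 10)
  expect_equal(unname(p0[["LTS"]]), 1)

  one <- true_model(baseline = list("LTS->W" = 0.3), censor_hazard = 0)
  p1 <- daily_transition_probs(one, "LTS", ref, t = 0)
  expect_equal(unname(p1[["W"]]), 1 - exp(-0.3))
  expect_equal(sum(p1), 1)

  # two competing edges: oracle = numeric integral of the exit-time density
  h <- c(0.17, 0.05)
  two <- true_model(
    baseline = list("LTS->W" = h[1], "LTS->U" = h[2]),
    censor_hazard = 0
  )
  p2 <- daily_transition_probs(two, "LTS", ref, t = 5)
  for (k in 1:2) {
    p_int <- stats::integrate(
      function(s) h[k] * exp(-sum(h) * s),
      lower = 0, upper = 1
    )$value
    expect_equal(unname(p2[[c("W", "U")[k]]]), p_int, tolerance = 1e-8)
  }
  expect_equal(sum(p2), 1)

  # absorbing state never leaves
  pd <- daily_transition_probs(two, "D", ref, t = 5)
  expect_equal(unname(pd[["D"]]), 1)
})

test_that("single pathways respect zero hazards, absorption, determinism", {
  ref <- toy_person()
  zero <- true_model(baseline = list(), censor_hazard = 0)
  path <- simulate_pathway(zero, ref, seed = 1)
  expect_true(all(path$state == "LTS"))
  expect_equal(nrow(path), 366L)

  absorbing <- true_model(baseline = list("LTS->D" = 0.2), censor_hazard = 0)
  pd <- simulate_pathway(absorbing, ref, seed = 2)
  hit <- which(pd$state == "D")
  expect_gt(length(hit), 0)
  expect_true(all(pd$state[seq(min(hit), nrow(pd))] == "D"))

  p1 <- simulate_pathway(toy_true_model(), ref, seed = 9)
  p2 <- simulate_pathway(toy_true_model(), ref, seed = 9)
  expect_identical(p1, p2)
})

test_that("occupation probabilities are a distribution and hit sure limits", {
  ref <- toy_person()
  absorbing <- true_model(baseline = list("LTS->D" = 10), censor_hazard = 0)
  occ <- predict_state_occupation(absorbing, ref, n_reps = 200, seed = 3)
  expect_equal(occ$P_D, 1)

  people <- dplyr::bind_rows(
    toy_person(1L), toy_person(2L, gender = "male"),
    toy_person(3L, prior_unemp = "two_plus")
  )
  occ2 <- predict_state_occupation(toy_true_model(), people,
    n_reps = 500, seed = 4
  )
  P <- as.matrix(occ2[, paste0("P_", lts_states())])
  expect_true(all(P >= 0 & P <= 1))
  expect_equal(unname(rowSums(P)), rep(1, 3))
  # same covariate pattern -> identical prediction rows
  occ3 <- predict_state_occupation(
    toy_true_model(), dplyr::bind_rows(toy_person(1L), toy_person(9L)),
    n_reps = 300, seed = 5
  )
  expect_equal(
    as.numeric(occ3[1, paste0("P_", lts_states())]),
    as.numeric(occ3[2, paste0("P_", lts_states())])
  )
})

test_that("the oracle reduces to matrix powers for homogeneous chains", {
  ref <- toy_person()
  zero <- true_model(baseline = list(), censor_hazard = 0)
  orc0 <- markov_oracle(zero, ref)
  expect_equal(orc0$P_LTS, 1)

  model <- toy_true_model()
  orc <- markov_oracle(model, ref, horizon = 365)
  # time-homogeneous: equals the 365th power of the one-step matrix
  probs <- daily_transition_probs(model, "LTS", ref, t = 0)
  states <- lts_states()
  M <- diag(6)
  dimnames(M) <- list(states, states)
  for (s in states[states != "D"]) {
    p <- daily_transition_probs(model, s, ref, t = 0)
    M[s, ] <- 0
    for (nm in names(p)) M[s, nm] <- M[s, nm] + p[[nm]]
  }
  v <- c(1, 0, 0, 0, 0, 0)
  for (i in 1:365) v <- as.vector(v %*% M)
  expect_equal(
    as.numeric(orc[1, paste0("P_", states)]), v,
    tolerance = 1e-10
  )
})

test_that("DES agrees with the oracle within Monte-Carlo error", {
  people <- dplyr::bind_rows(toy_person(1L), toy_person(2L, gender = "male"))
  n_reps <- 4000L
  des <- predict_state_occupation(toy_true_model(), people,
    n_reps = n_reps, seed = 6
  )
  orc <- markov_oracle(toy_true_model(), people)
  for (i in 1:2) {
    for (st in lts_states()) {
      p <- orc[[paste0("P_", st)]][i]
      se <- sqrt(max(p * (1 - p), 1e-7) / n_reps)
      expect_lt(abs(des[[paste0("P_", st)]][i] - p), 3 * se + 1e-9)
    }
  }
})

test_that("DES-oracle agreement holds across randomized hazard settings", {
  set.seed(71)
  edges <- lts_transitions()$edge
  n_reps <- 1500L
  failures <- 0L
  checks <- 0L
  for (rep in 1:12) {
    k <- sample(5:12, 1)
    baseline <- as.list(stats::runif(k, 0, 0.02))
    names(baseline) <- sample(edges, k)
    model <- true_model(baseline = baseline, censor_hazard = 0)
    des <- predict_state_occupation(model, toy_person(),
      n_reps = n_reps, seed = 100 + rep
    )
    orc <- markov_oracle(model, toy_person())
    for (st in lts_states()) {
      p <- orc[[paste0("P_", st)]]
      se <- sqrt(max(p * (1 - p), 1e-9) / n_reps)
      checks <- checks + 1L
      if (abs(des[[paste0("P_", st)]] - p) > 3 * se + 1e-9) {
        failures <- failures + 1L
      }
    }
  }
  # 3-sigma bands should cover in at least 99% of cases
  expect_lte(failures / checks, 0.01)
})

test_that("scaling up disability hazards raises oracle P(D)", {
  base <- toy_true_model()
  p_before <- markov_oracle(base, toy_person())$P_D
  scaled <- base
  scaled$baseline[["LTS->D"]]$rate <- scaled$baseline[["LTS->D"]]$rate * 4
  p_after <- markov_oracle(scaled, toy_person())$P_D
  expect_gt(p_after, p_before)
})

test_that("fitted null-covariate DES reproduces empirical day-365 frequencies", {
  cfg <- generator_config(2500, seed = 72)
  cov <- sample_covariates(cfg)
  hist <- simulate_histories(cov, true_model_null(censor_hazard = 0), cfg)
  tl <- derive_timeline(hist$spells, hist$total_days, persons = cov$person_id)
  cohort <- assemble_cohort(tl, cov, inclusion_window = c(365, 365))
  marked <- mark_initial_lts(tl, dplyr::select(cohort, person_id, index_day))
  set <- suppressWarnings(fit_transition_models(marked, cohort))
  occ <- predict_state_occupation(set, cohort, n_reps = 400, seed = 73)
  emp <- prop.table(table(factor(cohort$outcome, levels = lts_states())))
  for (st in lts_states()) {
    p <- emp[[st]]
    pred <- mean(occ[[paste0("P_", st)]])
    tol <- 3 * sqrt(max(p * (1 - p), 1e-6) / nrow(cohort)) + 0.01
    expect_lt(abs(pred - p), tol)
  }
})
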