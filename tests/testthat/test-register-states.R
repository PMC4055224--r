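# Spell -> timeline -> cohort derivation.

test_that("gaps become work and sickness maps to SA", {
  spells <- tibble::tibble(
    person_id = 1L, spell_type = "SICK", start_day = 0L, end_day = 40L
  )
  tl <- derive_timeline(spells, horizon = 100)
  expect_equal(tl$state, c("SA", "W"))
  expect_equal(tl$start_day, c(0L, 40L))
  expect_equal(tl$end_day, c(40L, 100L))
})

test_that("disability absorbs: later spells are ignored", {
  spells <- tibble::tibble(
    person_id = 1L,
    spell_type = c("DISAB", "UNEMP"),
    start_day = c(10L, 30L), end_day = c(20L, 40L)
  )
  tl <- derive_timeline(spells, horizon = 100)
  expect_equal(tl$state, c("W", "D"))
  expect_equal(tl$start_day, c(0L, 10L))
  expect_equal(tl$end_day, c(10L, 100L))
})

test_that("overlapping spells are a data error naming the person", {
  spells <- tibble::tibble(
    person_id = c(7L, 7L), spell_type = "SICK",
    start_day = c(0L, 5L), end_day = c(10L, 15L)
  )
  expect_error(derive_timeline(spells, horizon = 100), "7")
})

test_that("derived timelines round-trip the generator's state sequence", {
  cfg <- generator_config(400, seed = 21)
  cov <- sample_covariates(cfg)
  hist <- simulate_histories(cov, true_model_growth(), cfg)
  tl <- derive_timeline(hist$spells, hist$total_days,
    censor = hist$censor, persons = cov$person_id
  )
  marked <- mark_initial_lts(
    tl, tibble::tibble(person_id = cov$person_id, index_day = 365L)
  )
  expect_equal(sort_runs(marked), sort_runs(hist$truth))
})

test_that("initial episode finding honours the 28-day threshold and window", {
  mk <- function(len, start = 400L) {
    derive_timeline(
      tibble::tibble(
        person_id = 1L, spell_type = "SICK",
        start_day = start, end_day = start + len
      ),
      horizon = 1200
    )
  }
  expect_equal(nrow(find_initial_lts(mk(27L), c(365, 800))), 0L)
  idx <- find_initial_lts(mk(28L), c(365, 800))
  expect_equal(idx$index_day, 400L)

  # eligible spell in the buffer year is skipped in favour of a later one
  spells <- tibble::tibble(
    person_id = 1L, spell_type = "SICK",
    start_day = c(100L, 500L), end_day = c(140L, 530L)
  )
  tl <- derive_timeline(spells, horizon = 1200)
  expect_equal(find_initial_lts(tl, c(365, 800))$index_day, 500L)
})

test_that("look-back counting bins episodes like the register derivation", {
  tl <- toy_timeline(
    1L,
    c("W", "U", "W", "SA", "W", "U", "W", "SA"),
    c(0, 50, 70, 100, 130, 200, 260, 400),
    c(50, 70, 100, 130, 200, 260, 400, 500)
  )
  lb <- derive_lookback(tl, tibble::tibble(person_id = 1L, index_day = 400L))
  expect_equal(as.character(lb$prior_sa), "one_plus")
  expect_equal(as.character(lb$prior_unemp), "two_plus")

  none <- derive_timeline(
    tibble::tibble(
      person_id = 1L, spell_type = "SICK", start_day = 400L, end_day = 440L
    ),
    horizon = 800
  )
  lb2 <- derive_lookback(none, tibble::tibble(person_id = 1L, index_day = 400L))
  expect_equal(as.character(lb2$prior_sa), "none")
  expect_equal(as.character(lb2$prior_unemp), "none")

  expect_error(
    derive_lookback(tl, tibble::tibble(person_id = 1L, index_day = 100L)),
    "buffer"
  )
})

test_that("look-back counts equal a brute-force daily run scan", {
  set.seed(31)
  for (rep in 1:20) {
    n_sp <- sample(0:6, 1)
    spells <- tibble::tibble(
      person_id = integer(0), spell_type = character(0),
      start_day = integer(0), end_day = integer(0)
    )
    day <- 0L
    for (k in seq_len(n_sp)) {
      day <- day + sample(5:80, 1)
      len <- sample(3:60, 1)
      spells <- dplyr::bind_rows(spells, tibble::tibble(
        person_id = 1L,
        spell_type = sample(c("SICK", "UNEMP", "TEMPOUT"), 1),
        start_day = day, end_day = day + len
      ))
      day <- day + len
    }
    horizon <- 900L
    index <- 420L
    spells <- dplyr::filter(spells, end_day <= horizon)
    tl <- derive_timeline(spells, horizon, persons = 1L)
    lb <- derive_lookback(tl, tibble::tibble(person_id = 1L, index_day = index))

    # oracle: expand to a day vector and count maximal runs touching window
    days <- rep("W", horizon)
    for (i in seq_len(nrow(spells))) {
      st <- c(SICK = "SA", UNEMP = "U", TEMPOUT = "TO")[[spells$spell_type[i]]]
      days[(spells$start_day[i] + 1):spells$end_day[i]] <- st
    }
    count_runs <- function(state) {
      r <- rle(days)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths # 0-based
      sum(r$values == state & ends > index - 365 & starts < index)
    }
    exp_sa <- if (count_runs("SA") >= 1) "one_plus" else "none"
    nu <- count_runs("U")
    exp_u <- if (nu >= 2) "two_plus" else if (nu == 1) "one" else "none"
    expect_equal(as.character(lb$prior_sa), exp_sa)
    expect_equal(as.character(lb$prior_unemp), exp_u)
  }
})

test_that("one-year outcomes read the day-365 state or censoring", {
  tl <- toy_timeline(1L, c("SA", "W"), c(400, 440), c(440, 1000))
  marked <- mark_initial_lts(tl, tibble::tibble(person_id = 1L, index_day = 400L))
  out <- outcome_at_one_year(
    marked, tibble::tibble(person_id = 1L, index_day = 400L)
  )
  expect_equal(out$outcome, "W")

  tlc <- toy_timeline(2L, c("SA"), 400, 500, censor_day = 500L)
  outc <- outcome_at_one_year(
    tlc, tibble::tibble(person_id = 2L, index_day = 400L)
  )
  expect_equal(outc$outcome, "censored")
})

test_that("transition counting matches paths, flags illegal moves", {
  tl <- toy_timeline(
    1L, c("LTS", "W", "SA"), c(0, 50, 200), c(50, 200, 400)
  )
  counts <- count_transitions(tl)
  expect_equal(sum(counts$n), 2L)
  expect_equal(counts$n[counts$edge == "LTS->W"], 1L)
  expect_equal(counts$n[counts$edge == "W->SA"], 1L)

  still <- toy_timeline(1L, "W", 0, 400)
  expect_true(all(count_transitions(still)$n == 0L))

  bad <- toy_timeline(1L, c("D", "W"), c(0, 50), c(50, 100))
  expect_error(count_transitions(bad), "absorbing")
})

test_that("transition counts equal the generator's event log", {
  cfg <- generator_config(500, seed = 22)
  cov <- sample_covariates(cfg)
  hist <- simulate_histories(cov, true_model_growth(), cfg)
  tl <- derive_timeline(hist$spells, hist$total_days,
    censor = hist$censor, persons = cov$person_id
  )
  marked <- mark_initial_lts(
    tl, tibble::tibble(person_id = cov$person_id, index_day = 365L)
  )
  # follow-up window only: look-back boundaries are not generated events
  counts <- count_transitions(marked, window = c(365, 730))
  logged <- dplyr::count(hist$events, from, to)
  cmp <- dplyr::left_join(counts, logged, by = c("from", "to"))
  expect_equal(cmp$n.x, dplyr::coalesce(cmp$n.y, 0L))
})

test_that("cohort assembly produces the full covariate + outcome schema", {
  cfg <- generator_config(300, seed = 23)
  cov <- sample_covariates(cfg)
  hist <- simulate_histories(cov, true_model_growth(), cfg)
  tl <- derive_timeline(hist$spells, hist$total_days,
    censor = hist$censor, persons = cov$person_id
  )
  cohort <- assemble_cohort(tl, cov, inclusion_window = c(365, 365))
  expect_true(all(c(
    "person_id", "index_day", names(covariate_schema()), "outcome"
  ) %in% names(cohort)))
  expect_true(all(cohort$outcome %in% c(lts_states(), "censored")))
  # outcome frequencies among non-censored form a distribution over 6 states
  tab <- prop.table(table(cohort$outcome[cohort$outcome != "censored"]))
  expect_equal(sum(tab), 1)
})
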