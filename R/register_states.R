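# Spell records -> daily state timelines -> cohort rows.
#
# Timelines are represented compactly as maximal runs: one row per maximal
# interval of days a person spends in one state, half-open [start_day,
# end_day) on a 0-based day grid. The union of a person's runs tiles the
# observation window exactly (work = registered-benefit-free days), clipped
# at the censoring day when one exists.

#' Derive daily state timelines from spell records
#'
#' Maps benefit spells to states (`SICK` -> `SA`, `UNEMP` -> `U`, `DISAB` ->
#' `D`, `TEMPOUT` -> `TO`), fills all registered-benefit-free days with `W`,
#' enforces the absorbing disability rule (every day at or after the first
#' `DISAB` spell start is `D`, later spells are ignored), and clips each
#' person's timeline at their censoring day. The initial long-term sickness
#' episode is labelled `SA` like any other sickness at this stage; use
#' [mark_initial_lts()] once index days are known.
#'
#' @param spells Tibble with columns `person_id`, `spell_type` in
#'   `SICK`/`UNEMP`/`DISAB`/`TEMPOUT`, `start_day`, `end_day` (half-open,
#'   `end_day > start_day`, non-overlapping within person).
#' @param horizon Total number of observed days; runs are clipped to
#'   `[0, horizon)`.
#' @param censor Optional tibble `person_id`, `censor_day`.
#' @param persons Optional vector of person ids to include even when they
#'   have no spells (their whole window is `W`). Defaults to the ids present
#'   in `spells`.
#' @return Tibble `person_id`, `state`, `start_day`, `end_day`,
#'   `censor_day` (`NA` when not truncated), one row per maximal run.
#' @export
derive_timeline <- function(spells, horizon, censor = NULL, persons = NULL) {
  assert_columns(spells, c("person_id", "spell_type", "start_day", "end_day"), "spells")
  bad_type <- setdiff(unique(spells$spell_type), names(SPELL_STATE))
  if (length(bad_type) > 0L) {
    abort(paste0("unknown spell_type: ", paste(bad_type, collapse = ", ")))
  }
  if (any(spells$end_day <= spells$start_day)) {
    abort("spells must satisfy end_day > start_day")
  }
  spells <- arrange(spells, .data$person_id, .data$start_day)
  overlap <- spells |>
    group_by(.data$person_id) |>
    filter(.data$start_day < lag(.data$end_day, default = -1L)) |>
    ungroup()
  if (nrow(overlap) > 0L) {
    abort(paste0(
      "overlapping spells for person(s) ",
      paste(unique(overlap$person_id), collapse = ", "),
      " (e.g. at day ", overlap$start_day[[1L]], ")"
    ))
  }
  persons <- persons %||% unique(spells$person_id)
  censor <- censor %||% tibble(person_id = persons[0], censor_day = integer(0))

  # absorbing disability: truncate everything at the first DISAB start and
  # append a single D run to the end of the window
  d_first <- spells |>
    filter(.data$spell_type == "DISAB") |>
    group_by(.data$person_id) |>
    slice_min(.data$start_day, n = 1L, with_ties = FALSE) |>
    ungroup() |>
    select("person_id", d0 = "start_day")
  runs <- spells |>
    left_join(d_first, by = "person_id") |>
    filter(is.na(.data$d0) | .data$start_day < .data$d0) |>
    mutate(end_day = pmin(.data$end_day, coalesce(.data$d0, .data$end_day))) |>
    mutate(state = unname(SPELL_STATE[.data$spell_type])) |>
    select("person_id", "state", "start_day", "end_day")
  runs <- bind_rows(
    runs,
    d_first |>
      filter(.data$d0 < horizon) |>
      mutate(state = "D", start_day = .data$d0, end_day = as.integer(horizon)) |>
      select("person_id", "state", "start_day", "end_day")
  ) |>
    filter(.data$start_day < horizon, .data$end_day > 0L) |>
    mutate(
      start_day = pmax(.data$start_day, 0L),
      end_day = pmin(.data$end_day, as.integer(horizon))
    )

  runs <- fill_work_runs(runs, persons, censor, horizon) |>
    filter(.data$end_day > .data$start_day)
  # clip at censoring and merge adjacent same-state runs
  runs <- runs |>
    left_join(censor, by = "person_id") |>
    filter(is.na(.data$censor_day) | .data$start_day < .data$censor_day) |>
    mutate(end_day = pmin(.data$end_day, coalesce(.data$censor_day, .data$end_day))) |>
    arrange(.data$person_id, .data$start_day) |>
    group_by(.data$person_id) |>
    mutate(new_run = cumsum(
      .data$state != lag(.data$state, default = "<none>") |
        .data$start_day != lag(.data$end_day, default = -1L)
    )) |>
    group_by(.data$person_id, .data$censor_day, .data$new_run, .data$state) |>
    summarise(
      start_day = min(.data$start_day), end_day = max(.data$end_day),
      .groups = "drop"
    ) |>
    select("person_id", "state", "start_day", "end_day", "censor_day") |>
    arrange(.data$person_id, .data$start_day)
  runs
}

SPELL_STATE <- c(SICK = "SA", UNEMP = "U", DISAB = "D", TEMPOUT = "TO")

#' Find each person's initial long-term sickness episode
#'
#' Scans the sickness runs of a timeline for the first episode of at least
#' `min_days` consecutive sickness days whose start lies inside the
#' inclusion window. The window must exclude the buffer year so that a full
#' 365-day look-back exists for every included person. At most one index is
#' returned per person (the first eligible episode).
#'
#' @param timeline Output of [derive_timeline()].
#' @param inclusion_window Numeric length-2 vector `c(first, last)`: eligible
#'   episode start days (closed interval).
#' @param min_days Minimum episode length in days (28 = 4 weeks).
#' @return Tibble `person_id`, `index_day`; persons without an eligible
#'   episode are absent.
#' @export
find_initial_lts <- function(timeline, inclusion_window, min_days = 28L) {
  stopifnot(length(inclusion_window) == 2L)
  timeline |>
    filter(
      .data$state == "SA",
      .data$end_day - .data$start_day >= min_days,
      .data$start_day >= inclusion_window[[1L]],
      .data$start_day <= inclusion_window[[2L]]
    ) |>
    group_by(.data$person_id) |>
    summarise(index_day = min(.data$start_day), .groups = "drop")
}

#' Relabel initial episodes as LTS
#'
#' Splits/relabels each indexed person's sickness run containing the index
#' day so that days from the index day until the first transition are `LTS`.
#' Sickness before the index day (and any recurrent sickness after leaving
#' `LTS`) stays `SA`.
#'
#' @param timeline Output of [derive_timeline()].
#' @param index Tibble `person_id`, `index_day` from [find_initial_lts()].
#' @return Timeline tibble with `LTS` runs marked.
#' @export
mark_initial_lts <- function(timeline, index) {
  assert_columns(index, c("person_id", "index_day"), "index")
  marked <- timeline |>
    left_join(index, by = "person_id") |>
    mutate(hit = !is.na(.data$index_day) & .data$state == "SA" &
      .data$start_day <= .data$index_day & .data$end_day > .data$index_day)
  pre <- marked |>
    filter(.data$hit, .data$start_day < .data$index_day) |>
    mutate(end_day = .data$index_day)
  lts <- marked |>
    filter(.data$hit) |>
    mutate(state = "LTS", start_day = .data$index_day)
  bind_rows(filter(marked, !.data$hit), pre, lts) |>
    select("person_id", "state", "start_day", "end_day", "censor_day") |>
    arrange(.data$person_id, .data$start_day)
}

#' Derive look-back covariates
#'
#' Counts distinct completed episodes (maximal runs) of sickness absence and
#' unemployment intersecting the 365 days before each person's index day,
#' and bins them into the schema categories: prior sickness absence `none` /
#' `one_plus`, prior unemployment `none` / `one` / `two_plus`.
#'
#' @param timeline Output of [derive_timeline()] (unmarked or marked).
#' @param index Tibble `person_id`, `index_day`; every `index_day` must be
#'   >= `lookback_days`.
#' @param lookback_days Look-back window length (365).
#' @return Tibble `person_id`, `prior_sa`, `prior_unemp` (factors).
#' @export
derive_lookback <- function(timeline, index, lookback_days = 365L) {
  assert_columns(index, c("person_id", "index_day"), "index")
  if (any(index$index_day < lookback_days)) {
    abort("every index_day must be >= lookback_days (buffer-year precondition)")
  }
  schema <- covariate_schema()
  counts <- timeline |>
    inner_join(index, by = "person_id") |>
    filter(
      .data$state %in% c("SA", "U"),
      .data$end_day > .data$index_day - lookback_days,
      .data$start_day < .data$index_day
    ) |>
    count(.data$person_id, .data$state) |>
    tidyr::pivot_wider(names_from = "state", values_from = "n", values_fill = 0L)
  joined <- left_join(index, counts, by = "person_id")
  if (!"SA" %in% names(joined)) joined$SA <- 0L
  if (!"U" %in% names(joined)) joined$U <- 0L
  joined |>
    mutate(
      n_sa = coalesce(.data$SA, 0L),
      n_u = coalesce(.data$U, 0L),
      prior_sa = factor(
        ifelse(.data$n_sa >= 1L, "one_plus", "none"),
        levels = schema$prior_sa
      ),
      prior_unemp = factor(
        dplyr::case_when(
          .data$n_u >= 2L ~ "two_plus",
          .data$n_u == 1L ~ "one",
          TRUE ~ "none"
        ),
        levels = schema$prior_unemp
      )
    ) |>
    select("person_id", "prior_sa", "prior_unemp")
}

#' One-year outcome state
#'
#' Reads off the state occupied exactly 365 days after the index day, or
#' `"censored"` when observation was truncated on or before that day.
#'
#' @inheritParams derive_lookback
#' @param horizon_days Prediction horizon (365).
#' @return Tibble `person_id`, `outcome` (character: a state label or
#'   `"censored"`).
#' @export
outcome_at_one_year <- function(timeline, index, horizon_days = 365L) {
  assert_columns(index, c("person_id", "index_day"), "index")
  at <- timeline |>
    inner_join(index, by = "person_id") |>
    mutate(target = .data$index_day + horizon_days) |>
    filter(.data$start_day <= .data$target, .data$end_day > .data$target) |>
    select("person_id", outcome = "state", "censor_day", "target")
  out <- index |>
    left_join(at, by = "person_id") |>
    mutate(outcome = ifelse(
      !is.na(.data$censor_day) & .data$censor_day <= .data$index_day + horizon_days,
      "censored", .data$outcome
    ))
  cens_elsewhere <- timeline |>
    distinct(.data$person_id, .data$censor_day)
  out <- out |>
    select("person_id", "outcome") |>
    left_join(cens_elsewhere, by = "person_id") |>
    mutate(outcome = coalesce(
      .data$outcome,
      ifelse(!is.na(.data$censor_day), "censored", NA_character_)
    )) |>
    select("person_id", "outcome")
  if (any(is.na(out$outcome))) {
    abort("timeline does not cover index_day + horizon_days for some persons")
  }
  out
}

#' Count observed transitions
#'
#' Tabulates every day-boundary state change in the timelines over the 20
#' legal edges of the multi-state model. Changes out of the absorbing
#' disability state, or into `LTS`, are data errors.
#'
#' @param timeline A (marked or unmarked) timeline tibble.
#' @param window Optional restriction on which transitions to count: either
#'   a numeric `c(lo, hi)` (count transitions landing on day `d` with
#'   `lo < d <= hi`) or a tibble `person_id`, `lo`, `hi` for per-person
#'   windows (e.g. `(index_day, index_day + 365]`). Boundaries *into* `LTS`
#'   mark cohort entry and are never counted (the model has no edges into
#'   `LTS`).
#' @return Tibble `from`, `to`, `edge`, `n` over all 20 legal edges (zero
#'   rows included).
#' @export
count_transitions <- function(timeline, window = NULL) {
  moves <- timeline |>
    arrange(.data$person_id, .data$start_day) |>
    group_by(.data$person_id) |>
    mutate(
      to = lead(.data$state),
      adjacent = lead(.data$start_day) == .data$end_day
    ) |>
    ungroup() |>
    filter(!is.na(.data$to), .data$adjacent) |>
    mutate(day = .data$end_day, from = .data$state) |>
    # the boundary into LTS is the cohort-entry marker, not a transition of
    # the multi-state model (no edges lead into LTS)
    filter(.data$to != "LTS")
  if (!is.null(window)) {
    if (is.data.frame(window)) {
      assert_columns(window, c("person_id", "lo", "hi"), "window")
      moves <- moves |>
        inner_join(window, by = "person_id") |>
        filter(.data$day > .data$lo, .data$day <= .data$hi)
    } else {
      stopifnot(length(window) == 2L)
      moves <- filter(moves, .data$day > window[[1L]], .data$day <= window[[2L]])
    }
  }
  if (any(moves$from == "D")) {
    bad <- unique(moves$person_id[moves$from == "D"])
    abort(paste0(
      "transition out of absorbing state D observed for person(s) ",
      paste(bad[seq_len(min(5L, length(bad)))], collapse = ", ")
    ))
  }
  illegal <- moves |>
    filter(!edge_key(.data$from, .data$to) %in% lts_transitions()$edge)
  if (nrow(illegal) > 0L) {
    abort(paste0(
      "illegal transition(s) observed: ",
      paste(unique(edge_key(illegal$from, illegal$to)), collapse = ", ")
    ))
  }
  lts_transitions() |>
    left_join(
      count(moves, .data$from, .data$to),
      by = c("from", "to")
    ) |>
    mutate(n = coalesce(.data$n, 0L))
}

#' Assemble the analysis cohort
#'
#' Runs episode finding, look-back derivation and outcome reading, and joins
#' the baseline covariate table, producing one row per included person.
#'
#' @param timeline Output of [derive_timeline()].
#' @param baseline_covariates Tibble with `person_id` and the five baseline
#'   covariates (`gender`, `age_group`, `socio_economic`, `job_type`,
#'   `chronic_disease`).
#' @param inclusion_window Passed to [find_initial_lts()].
#' @param min_days Minimum initial episode length (28).
#' @param lookback_days,horizon_days Window lengths (365 each).
#' @return Cohort tibble: `person_id`, `index_day`, the seven covariates
#'   (`prior_sa`/`prior_unemp` derived from the timeline, not taken from any
#'   generator bookkeeping), and `outcome` (state label or `"censored"`).
#' @export
assemble_cohort <- function(timeline, baseline_covariates, inclusion_window,
                            min_days = 28L, lookback_days = 365L,
                            horizon_days = 365L) {
  baseline <- c("gender", "age_group", "socio_economic", "job_type", "chronic_disease")
  assert_columns(baseline_covariates, c("person_id", baseline), "baseline covariates")
  index <- find_initial_lts(timeline, inclusion_window, min_days)
  if (nrow(index) == 0L) {
    warn("no eligible initial long-term sickness episodes found")
  }
  marked <- mark_initial_lts(timeline, index)
  index |>
    left_join(select(baseline_covariates, "person_id", all_of(baseline)),
      by = "person_id"
    ) |>
    left_join(derive_lookback(marked, index, lookback_days), by = "person_id") |>
    left_join(outcome_at_one_year(marked, index, horizon_days), by = "person_id")
}
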