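# Synthetic register-spell generator: covariates from configurable margins,
# look-back episodes planted to match the sampled prior-SA / prior-unemployment
# categories, and a forward daily trajectory driven by a known true_model.

#' Generator configuration
#'
#' @param n_persons Number of persons to generate (>= 0).
#' @param margins Marginal category probabilities per covariate, as produced
#'   by [default_covariate_margins()]. Probabilities per covariate must sum
#'   to 1.
#' @param lookback_days Length of the covariate look-back window (365).
#' @param horizon_days Follow-up horizon after the index day (365).
#' @param lts_min_days Minimum length of the initial long-term sickness
#'   episode (28 days = 4 weeks); the generator holds persons in `LTS` for
#'   this many days before exit hazards apply.
#' @param min_sick_spell Minimum length of *registered* sickness spells
#'   planted in the look-back window (14 days; shorter absence does not
#'   reach the register).
#' @param seed Integer root seed.
#' @param n_pathway_reps Default number of simulated pathways per person for
#'   the discrete event simulation (10,000).
#'
#' @return An object of class `generator_config`.
#' @export
generator_config <- function(n_persons,
                             margins = default_covariate_margins(),
                             lookback_days = 365L,
                             horizon_days = 365L,
                             lts_min_days = 28L,
                             min_sick_spell = 14L,
                             seed = 1L,
                             n_pathway_reps = 10000L) {
  if (n_persons < 0) abort("n_persons must be >= 0")
  if (lts_min_days < 1) abort("lts_min_days must be >= 1")
  schema <- covariate_schema()
  assert_columns(as.list(margins), names(schema), "margins")
  for (nm in names(schema)) {
    p <- margins[[nm]]
    if (!setequal(names(p), schema[[nm]])) {
      abort(paste0("margins for `", nm, "` must be named by its levels"))
    }
    if (abs(sum(p) - 1) > 1e-6 || any(p < 0)) {
      abort(paste0("margins for covariate `", nm, "` do not sum to 1"))
    }
  }
  structure(
    list(
      n_persons = as.integer(n_persons), margins = margins,
      lookback_days = as.integer(lookback_days),
      horizon_days = as.integer(horizon_days),
      lts_min_days = as.integer(lts_min_days),
      min_sick_spell = as.integer(min_sick_spell),
      seed = as.integer(seed), n_pathway_reps = as.integer(n_pathway_reps)
    ),
    class = "generator_config"
  )
}

#' Sample baseline covariates from configured margins
#'
#' Draws all seven covariates independently from the marginal category
#' probabilities in `config`. The look-back covariates (`prior_sa`,
#' `prior_unemp`) sampled here are later *planted* into the look-back spell
#' history by [simulate_histories()], so deriving them back from the spells
#' reproduces these values exactly.
#'
#' @param config A [generator_config()].
#' @param seed Seed (defaults to `config$seed`).
#' @return Tibble with `person_id` and the seven covariate factor columns;
#'   zero rows (full schema) when `n_persons = 0`.
#' @export
sample_covariates <- function(config, seed = config$seed) {
  schema <- covariate_schema()
  n <- config$n_persons
  if (n == 0L) {
    out <- tibble(person_id = integer(0))
    for (nm in names(schema)) out[[nm]] <- factor(character(0), levels = schema[[nm]])
    return(out)
  }
  set.seed(seed)
  out <- tibble(person_id = seq_len(n))
  for (nm in names(schema)) {
    p <- config$margins[[nm]][schema[[nm]]]
    out[[nm]] <- factor(
      sample(schema[[nm]], n, replace = TRUE, prob = p),
      levels = schema[[nm]]
    )
  }
  out
}

# state codes used in the simulation matrices
STATE_CODES <- c(LTS = 1L, W = 2L, U = 3L, SA = 4L, D = 5L, TO = 6L)
SPELL_TYPES <- c(LTS = "SICK", SA = "SICK", U = "UNEMP", D = "DISAB", TO = "TEMPOUT")

#' Simulate register-like spell histories from a ground-truth model
#'
#' For each person: plants completed look-back episodes of registered
#' sickness absence and unemployment in the 365 days before the index day
#' (matching the sampled `prior_sa` / `prior_unemp` categories), starts an
#' initial long-term sickness episode at the index day, and steps the
#' trajectory forward one day at a time under competing exponential daily
#' hazards. Within a day, the stay probability is `exp(-sum(h))` and exit
#' probabilities are proportional to the per-transition hazards; disability
#' is absorbing; an independent daily censoring hazard right-truncates the
#' trajectory. Work is represented in the register convention as the absence
#' of spells.
#'
#' @param covariates Covariate table from [sample_covariates()].
#' @param model A [true_model()].
#' @param config A [generator_config()].
#' @param seed Seed (defaults to `config$seed + 1` so covariate sampling and
#'   trajectory simulation use distinct streams).
#' @return An object of class `spell_data`: a list with
#'   * `spells`: tibble `person_id`, `spell_type` (`SICK`/`UNEMP`/`DISAB`/
#'     `TEMPOUT`), `start_day`, `end_day` (half-open day intervals on the
#'     absolute grid where day 0 opens the look-back window and the index
#'     day is `lookback_days`),
#'   * `covariates`: the input covariate table,
#'   * `truth`: the generator's internal daily state sequence as maximal
#'     runs (`person_id`, `state`, `start_day`, `end_day`, `censor_day`),
#'   * `events`: log of every simulated transition (`person_id`, `day`,
#'     `from`, `to`),
#'   * `censor`: tibble `person_id`, `censor_day` (truncated persons only),
#'   * `config`, `model`.
#' @export
simulate_histories <- function(covariates, model, config,
                               seed = config$seed + 1L) {
  assert_columns(covariates, c("person_id", names(covariate_schema())), "covariates")
  n <- nrow(covariates)
  index_day <- config$lookback_days
  horizon <- config$horizon_days
  total_days <- config$lookback_days + horizon + 1L

  set.seed(seed)
  lookback <- plant_lookback(covariates, config)

  # forward simulation on the relative grid t = 0..horizon
  R <- baseline_rate_matrix(model, horizon) # 20 x horizon
  M <- hazard_multipliers(model, covariates) # n x 20
  edges <- lts_transitions()
  out_edges <- split(seq_len(nrow(edges)), edges$from)
  to_code <- STATE_CODES[edges$to]

  states <- matrix(NA_integer_, nrow = n, ncol = horizon + 1L)
  if (n > 0L) states[, 1L] <- STATE_CODES[["LTS"]]
  censor_rel <- rep(NA_integer_, n)
  p_cens <- 1 - exp(-model$censor_hazard)

  for (t in seq_len(horizon) - 1L) {
    cur <- states[, t + 1L]
    active <- which(!is.na(cur))
    if (length(active) == 0L) break
    if (p_cens > 0) {
      cens <- active[runif(length(active)) < p_cens]
      if (length(cens) > 0L) {
        censor_rel[cens] <- t + 1L
        active <- setdiff(active, cens)
      }
    }
    nxt <- cur
    for (st in names(out_edges)) {
      code <- STATE_CODES[[st]]
      idx <- active[cur[active] == code]
      if (length(idx) == 0L) next
      if (st == "LTS" && t < config$lts_min_days - 1L) {
        # a draw during day t lands at day t+1, so suppressing draws for
        # t < m-1 makes the shortest possible initial episode exactly m days
        next
      }
      e <- out_edges[[st]]
      rates <- M[idx, e, drop = FALSE] *
        rep(R[e, t + 1L], each = length(idx))
      tot <- rowSums(rates)
      stay <- exp(-tot)
      u <- runif(length(idx))
      moving <- which(u >= stay & tot > 0)
      if (length(moving) > 0L) {
        # allocate exits proportionally to per-transition hazards
        frac <- (u[moving] - stay[moving]) / (1 - stay[moving])
        cum <- rates[moving, , drop = FALSE] / tot[moving]
        for (k in seq_len(ncol(cum))[-1]) cum[, k] <- cum[, k - 1L] + cum[, k]
        cum[, ncol(cum)] <- 1 # close the last bin against rounding
        pick <- max.col(frac <= cum, ties.method = "first")
        nxt[idx[moving]] <- to_code[e[pick]]
      }
    }
    nxt[is.na(cur)] <- NA_integer_
    if (p_cens > 0 && length(censor_rel) > 0L) {
      nxt[!is.na(censor_rel) & censor_rel == t + 1L] <- NA_integer_
    }
    states[, t + 2L] <- nxt
  }

  truth_fwd <- encode_runs(states, offset = index_day)
  events <- encode_events(states, offset = index_day)
  censor <- tibble(
    person_id = covariates$person_id[which(!is.na(censor_rel))],
    censor_day = index_day + censor_rel[!is.na(censor_rel)]
  )

  truth_fwd$person_id <- covariates$person_id[truth_fwd$row]
  events$person_id <- covariates$person_id[events$row]

  truth <- bind_rows(lookback$runs, select(truth_fwd, -"row")) |>
    fill_work_runs(covariates$person_id, censor, total_days) |>
    left_join(censor, by = "person_id")

  spells <- truth |>
    filter(.data$state != "W") |>
    mutate(spell_type = unname(SPELL_TYPES[.data$state])) |>
    select("person_id", "spell_type", "start_day", "end_day") |>
    arrange(.data$person_id, .data$start_day)

  structure(
    list(
      spells = spells, covariates = covariates, truth = truth,
      events = select(events, "person_id", "day", "from", "to"),
      censor = censor, config = config, model = model,
      index_day = index_day, total_days = total_days
    ),
    class = "spell_data"
  )
}

# Plant completed look-back episodes on [0, index_day - 1) with >= 1 day
# gaps so that maximal-run counting recovers the sampled categories exactly.
plant_lookback <- function(covariates, config) {
  index_day <- config$lookback_days
  n <- nrow(covariates)
  n_sa <- as.integer(covariates$prior_sa == "one_plus")
  n_u <- c(none = 0L, one = 1L, two_plus = 2L)[as.character(covariates$prior_unemp)]
  pid <- sts <- st0 <- en0 <- vector("list", n)
  for (i in seq_len(n)) {
    k <- n_sa[i] + n_u[i]
    if (k == 0L) next
    lens <- c(
      if (n_sa[i] > 0L) sample(config$min_sick_spell:42L, n_sa[i], replace = TRUE),
      if (n_u[i] > 0L) sample(14L:70L, n_u[i], replace = TRUE)
    )
    st <- c(rep("SA", n_sa[i]), rep("U", n_u[i]))
    ord <- sample.int(k)
    lens <- lens[ord]
    st <- st[ord]
    # last occupied day <= index_day - 2: leaves a work day before the index
    free <- (index_day - 1L) - sum(lens) - (k - 1L)
    w <- runif(k + 1L)
    gaps <- floor(w / sum(w) * free)
    starts <- cumsum(c(gaps[1L], if (k > 1L) lens[-k] + 1L + gaps[2:k]))
    pid[[i]] <- rep(covariates$person_id[i], k)
    sts[[i]] <- st
    st0[[i]] <- starts
    en0[[i]] <- starts + lens
  }
  list(runs = tibble(
    person_id = as.integer(unlist(pid)) %||% integer(0),
    state = as.character(unlist(sts)) %||% character(0),
    start_day = as.integer(unlist(st0)) %||% integer(0),
    end_day = as.integer(unlist(en0)) %||% integer(0)
  ))
}

# Run-length encode the rows of a state-code matrix into half-open day runs.
encode_runs <- function(states, offset) {
  n <- nrow(states)
  labels <- names(STATE_CODES)
  if (n == 0L) {
    return(tibble(
      row = integer(0), state = character(0),
      start_day = integer(0), end_day = integer(0)
    ))
  }
  rows <- vals <- st0 <- en0 <- vector("list", n)
  for (i in seq_len(n)) {
    s <- states[i, ]
    s <- s[!is.na(s)]
    r <- rle(s)
    ends <- cumsum(r$lengths)
    rows[[i]] <- rep.int(i, length(ends))
    vals[[i]] <- r$values
    st0[[i]] <- offset + c(0L, ends[-length(ends)])
    en0[[i]] <- offset + ends
  }
  tibble(
    row = unlist(rows), state = labels[unlist(vals)],
    start_day = as.integer(unlist(st0)), end_day = as.integer(unlist(en0))
  )
}

# Fill uncovered days with W runs so each person's runs tile [0, limit)
# exactly, where limit is the censor day (if any) or the full window.
fill_work_runs <- function(runs, person_ids, censor, total_days) {
  limits <- tibble(person_id = person_ids, limit = as.integer(total_days)) |>
    left_join(censor, by = "person_id") |>
    mutate(limit = pmin(.data$limit, coalesce(.data$censor_day, .data$limit))) |>
    select("person_id", "limit")
  r <- runs |>
    arrange(.data$person_id, .data$start_day) |>
    group_by(.data$person_id) |>
    mutate(prev_end = lag(.data$end_day, default = 0L)) |>
    ungroup()
  inner_gaps <- r |>
    filter(.data$start_day > .data$prev_end) |>
    mutate(state = "W", end_day = .data$start_day, start_day = .data$prev_end) |>
    select("person_id", "state", "start_day", "end_day")
  trailing <- r |>
    group_by(.data$person_id) |>
    summarise(last_end = max(.data$end_day), .groups = "drop") |>
    right_join(limits, by = "person_id") |>
    mutate(last_end = coalesce(.data$last_end, 0L)) |>
    filter(.data$last_end < .data$limit) |>
    mutate(state = "W", start_day = .data$last_end, end_day = .data$limit) |>
    select("person_id", "state", "start_day", "end_day")
  bind_rows(select(r, "person_id", "state", "start_day", "end_day"),
    inner_gaps, trailing
  ) |>
    arrange(.data$person_id, .data$start_day)
}

encode_events <- function(states, offset) {
  n <- nrow(states)
  labels <- names(STATE_CODES)
  if (n == 0L || ncol(states) < 2L) {
    return(tibble(
      row = integer(0), person_id = integer(0), day = integer(0),
      from = character(0), to = character(0)
    ))
  }
  prev <- states[, -ncol(states), drop = FALSE]
  nxt <- states[, -1L, drop = FALSE]
  chg <- which(!is.na(prev) & !is.na(nxt) & prev != nxt, arr.ind = TRUE)
  tibble(
    row = chg[, 1L],
    person_id = NA_integer_,
    day = offset + chg[, 2L], # transition lands on this day
    from = labels[prev[chg]],
    to = labels[nxt[chg]]
  ) |> arrange(.data$row, .data$day)
}

#' @export
print.spell_data <- function(x, ...) {
  cat("<spell_data>\n")
  cat("  persons:", nrow(x$covariates), "\n")
  cat("  spells:", nrow(x$spells), "\n")
  cat("  transitions logged:", nrow(x$events), "\n")
  cat("  censored persons:", nrow(x$censor), "\n")
  cat("  index day:", x$index_day, " observed days: [0,", x$total_days, ")\n")
  invisible(x)
}

#' Write / read spell data as plain CSV
#'
#' Writes `spells.csv` (person_id, spell_type, start_day, end_day),
#' `covariates.csv` and `config.yaml` into `dir`.
#'
#' @param x A `spell_data` object.
#' @param dir Output directory (created if needed).
#' @return `x` invisibly.
#' @export
write_spell_data <- function(x, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_csv(x$spells, file.path(dir, "spells.csv"))
  readr::write_csv(x$covariates, file.path(dir, "covariates.csv"))
  readr::write_csv(x$censor, file.path(dir, "censor.csv"))
  cfg <- x$config
  cfg$margins <- map(cfg$margins, as.list)
  yaml::write_yaml(unclass(cfg), file.path(dir, "config.yaml"))
  invisible(x)
}

#' @rdname write_spell_data
#' @export
read_spells <- function(dir) {
  readr::read_csv(
    file.path(dir, "spells.csv"),
    col_types = readr::cols(
      person_id = readr::col_integer(), spell_type = readr::col_character(),
      start_day = readr::col_integer(), end_day = readr::col_integer()
    )
  )
}
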