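# Discrete event simulation of individual pathways through the six-state
# model, plus an exact Markov matrix-product oracle for the same day-grid
# process. Both consume either a fitted transition_model_set (daily hazard
# increments = Breslow baseline jumps times the covariate hazard ratio) or a
# true_model (daily increments = the generating rates), so the DES can be
# verified exactly against known hazards.

# Common inputs: 20 x horizon baseline increments and n x 20 multipliers.
des_inputs <- function(object, newdata, horizon) {
  edges <- lts_transitions()$edge
  if (inherits(object, "true_model")) {
    list(
      inc = baseline_rate_matrix(object, horizon),
      mult = hazard_multipliers(object, newdata)
    )
  } else if (inherits(object, "transition_model_set")) {
    inc <- matrix(0, length(edges), horizon, dimnames = list(edges, NULL))
    mult <- matrix(1, nrow(newdata), length(edges), dimnames = list(NULL, edges))
    for (e in names(object$models)) {
      m <- object$models[[e]]
      inc[e, ] <- m$inc_vec[seq_len(horizon)]
      mult[, e] <- exp(linear_predictor(m, newdata))
    }
    list(inc = inc, mult = mult)
  } else {
    abort("`object` must be a transition_model_set or a true_model")
  }
}

#' One-day transition probabilities from a state
#'
#' Combines the daily hazard increments of all transitions out of
#' `current_state` into a single valid probability vector for the day step
#' `t -> t + 1`: the stay probability is `exp(-sum(d))` and the probability
#' of exiting to state `k` is `(d_k / sum(d)) * (1 - exp(-sum(d)))`, the
#' exact allocation for competing constant hazards over one day. The
#' absorbing state `D` returns stay probability 1.
#'
#' @param object A `transition_model_set` or `true_model`.
#' @param current_state One of the six state labels.
#' @param covariates Single-row tibble of covariates.
#' @param t Day index, `0 <= t < horizon`.
#' @param horizon Follow-up length (365).
#' @param lts_hold_days Days during which exits from `LTS` are suppressed
#'   (the generating process enforces the 4-week minimum episode this way;
#'   leave 0 for fitted models, where the data carry the constraint).
#' @return Named probability vector: first element the stay probability
#'   (named by `current_state`), then one element per reachable state; sums
#'   to 1.
#' @export
daily_transition_probs <- function(object, current_state, covariates, t,
                                   horizon = 365L, lts_hold_days = 0L) {
  stopifnot(length(t) == 1L, t >= 0, t < horizon)
  if (!current_state %in% lts_states()) {
    abort(paste0("unknown state: ", current_state))
  }
  if (current_state == "D") {
    return(c(D = 1))
  }
  tr <- lts_transitions()
  e <- which(tr$from == current_state)
  di <- des_inputs(object, covariates, horizon)
  d <- di$inc[e, t + 1L] * di$mult[1L, e]
  if (any(d < 0)) abort("internal error: negative hazard increment")
  if (current_state == "LTS" && t < lts_hold_days) d[] <- 0
  tot <- sum(d)
  stay <- exp(-tot)
  exits <- if (tot > 0) (d / tot) * (1 - stay) else rep(0, length(d))
  setNames(c(stay, exits), c(current_state, tr$to[e]))
}

# One vectorised day step shared by the generator-style samplers: `cur` are
# integer state codes (NA = inactive), `rates_for` returns the per-unit
# competing hazard matrix for a group of units in one state.
sample_next_state <- function(cur, out_edges, to_code, rates_for, hold_lts) {
  nxt <- cur
  for (st in names(out_edges)) {
    code <- STATE_CODES[[st]]
    idx <- which(!is.na(cur) & cur == code)
    if (length(idx) == 0L) next
    if (st == "LTS" && hold_lts) next
    e <- out_edges[[st]]
    rates <- rates_for(idx, e)
    tot <- rowSums(rates)
    stay <- exp(-tot)
    u <- runif(length(idx))
    moving <- which(u >= stay & tot > 0)
    if (length(moving) > 0L) {
      frac <- (u[moving] - stay[moving]) / (1 - stay[moving])
      cum <- rates[moving, , drop = FALSE] / tot[moving]
      for (k in seq_len(ncol(cum))[-1L]) cum[, k] <- cum[, k - 1L] + cum[, k]
      cum[, ncol(cum)] <- 1
      pick <- max.col(frac <= cum, ties.method = "first")
      nxt[idx[moving]] <- to_code[e[pick]]
    }
  }
  nxt
}

#' Simulate one pathway
#'
#' Draws a single daily pathway `Y(0), Y(1), ..., Y(horizon)` starting in
#' `LTS`, with one categorical draw per day from the combined one-day
#' transition probabilities ("no transition" included); `D` is absorbing.
#'
#' @inheritParams daily_transition_probs
#' @param seed Integer seed; the pathway is deterministic given the seed.
#' @return Tibble `day` (0..horizon), `state`.
#' @export
simulate_pathway <- function(object, covariates, seed = 1L, horizon = 365L,
                             lts_hold_days = 0L) {
  di <- des_inputs(object, covariates[1L, , drop = FALSE], horizon)
  tr <- lts_transitions()
  out_edges <- split(seq_len(nrow(tr)), tr$from)
  to_code <- STATE_CODES[tr$to]
  set.seed(seed)
  y <- integer(horizon + 1L)
  y[1L] <- STATE_CODES[["LTS"]]
  for (t in seq_len(horizon) - 1L) {
    y[t + 2L] <- sample_next_state(
      y[t + 1L], out_edges, to_code,
      function(idx, e) {
        matrix(di$inc[e, t + 1L] * di$mult[1L, e], nrow = 1L)
      },
      hold_lts = t < lts_hold_days
    )
  }
  tibble(day = 0:horizon, state = names(STATE_CODES)[y])
}

#' Per-person state-occupation probabilities by discrete event simulation
#'
#' The core long-horizon predictor: simulates `n_reps` daily pathways per
#' person from the fitted (or true) transition hazards and estimates the
#' probability of each state at day `horizon` as the fraction of pathways
#' ending there. Persons sharing a covariate pattern share one batch of
#' pathways (the prediction depends on covariates only); units are ordered
#' deterministically so results are reproducible given `seed`.
#'
#' @inheritParams daily_transition_probs
#' @param newdata Cohort-like tibble with `person_id` and covariates.
#' @param n_reps Simulated pathways per person (paper-scale default 10,000;
#'   scale down for quick exploration). Monte-Carlo standard error per state
#'   is at most `0.5 / sqrt(n_reps)`.
#' @param seed Integer seed.
#' @return Tibble `person_id`, `source = "DES"`, `n_reps`, and `P_<state>`
#'   columns over the six states; each row sums to 1.
#' @export
predict_state_occupation <- function(object, newdata, n_reps = 10000L,
                                     seed = 1L, horizon = 365L,
                                     lts_hold_days = 0L) {
  if (n_reps < 1L) abort("n_reps must be >= 1")
  di <- des_inputs(object, newdata, horizon)
  key <- apply(di$mult, 1L, paste, collapse = "\r")
  first <- !duplicated(key)
  mult_u <- di$mult[first, , drop = FALSE]
  pat <- match(key, key[first])
  P <- nrow(mult_u)

  tr <- lts_transitions()
  out_edges <- split(seq_len(nrow(tr)), tr$from)
  to_code <- STATE_CODES[tr$to]

  unit_pat <- rep(seq_len(P), each = n_reps)
  state <- rep.int(STATE_CODES[["LTS"]], P * n_reps)
  set.seed(seed)
  for (t in seq_len(horizon) - 1L) {
    state <- sample_next_state(
      state, out_edges, to_code,
      function(idx, e) {
        mult_u[unit_pat[idx], e, drop = FALSE] *
          rep(di$inc[e, t + 1L], each = length(idx))
      },
      hold_lts = t < lts_hold_days
    )
  }

  occ <- matrix(0, nrow = P, ncol = length(STATE_CODES))
  for (code in seq_along(STATE_CODES)) {
    occ[, code] <- tabulate(unit_pat[state == code], nbins = P) / n_reps
  }
  colnames(occ) <- paste0("P_", names(STATE_CODES))
  out <- tibble(
    person_id = newdata$person_id,
    source = "DES", n_reps = as.integer(n_reps)
  )
  bind_cols(out, as_tibble(occ[pat, , drop = FALSE]))
}

#' Exact day-365 occupation probabilities (Markov oracle)
#'
#' Multiplies the ordered product of the `horizon` daily one-step transition
#' matrices implied by [daily_transition_probs()], starting from the unit
#' vector on `LTS`. For the day-grid process this is exact, so it serves as
#' the verification oracle for the discrete event simulation.
#'
#' @inheritParams predict_state_occupation
#' @return Tibble `person_id`, `source = "oracle"`, and `P_<state>` columns.
#' @export
markov_oracle <- function(object, newdata, horizon = 365L, lts_hold_days = 0L) {
  di <- des_inputs(object, newdata, horizon)
  key <- apply(di$mult, 1L, paste, collapse = "\r")
  first <- !duplicated(key)
  mult_u <- di$mult[first, , drop = FALSE]
  pat <- match(key, key[first])

  tr <- lts_transitions()
  from_code <- STATE_CODES[tr$from]
  to_code <- STATE_CODES[tr$to]
  ns <- length(STATE_CODES)

  occ <- matrix(0, nrow = nrow(mult_u), ncol = ns,
    dimnames = list(NULL, paste0("P_", names(STATE_CODES)))
  )
  for (p in seq_len(nrow(mult_u))) {
    v <- c(1, rep(0, ns - 1L)) # e_LTS
    for (t in seq_len(horizon) - 1L) {
      d <- di$inc[, t + 1L] * mult_u[p, ]
      if (t < lts_hold_days) d[from_code == STATE_CODES[["LTS"]]] <- 0
      M <- diag(ns)
      for (s in unique(from_code)) {
        rows <- which(from_code == s)
        tot <- sum(d[rows])
        if (tot > 0) {
          stay <- exp(-tot)
          M[s, s] <- stay
          for (r in rows) {
            M[s, to_code[[r]]] <- M[s, to_code[[r]]] + d[[r]] / tot * (1 - stay)
          }
        }
      }
      if (any(abs(rowSums(M) - 1) > 1e-12)) {
        abort("internal error: transition-matrix row does not sum to 1")
      }
      v <- as.vector(v %*% M)
    }
    occ[p, ] <- v
  }
  bind_cols(
    tibble(person_id = newdata$person_id, source = "oracle"),
    as_tibble(occ[pat, , drop = FALSE])
  )
}
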