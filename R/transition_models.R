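# Counting-process risk sets per transition and transition-specific Cox
# proportional hazards models. All transitions share one clock: days since
# the index day (the start of the initial long-term sickness episode), with
# left truncation at sojourn entry. Competing exits from the same state are
# treated as censoring for each cause-specific fit. Ties are handled by
# Breslow's method (ties are massive on an integer day grid) and the
# baseline cumulative hazard is the Breslow estimator at the reference
# covariate pattern.

#' Build the counting-process risk set for one transition
#'
#' One record per maximal sojourn of a person in the transition's from-state
#' intersecting the follow-up window `(0, horizon]` on the common
#' days-since-index clock: entry (left-truncation time), exit, an event
#' indicator that is 1 only when the sojourn ends in the target state within
#' the window, and the person's baseline covariates.
#'
#' @param timeline Marked timeline (see [mark_initial_lts()]).
#' @param cohort Cohort tibble from [assemble_cohort()].
#' @param edge Transition, e.g. `"LTS->W"`.
#' @param horizon Follow-up length in days (365).
#' @return Tibble `person_id`, `entry`, `exit`, `event` plus the seven
#'   covariate columns; class `risk_set` with attributes `edge`, `horizon`.
#' @export
build_risk_sets <- function(timeline, cohort, edge, horizon = 365L) {
  if (!is_legal_edge(edge)) {
    abort(paste0("`", edge, "` is not one of the 20 legal transitions"))
  }
  ft <- split_edge(edge)
  covs <- names(covariate_schema())
  assert_columns(cohort, c("person_id", "index_day", covs), "cohort")
  sojourns <- timeline |>
    inner_join(select(cohort, "person_id", "index_day"), by = "person_id") |>
    arrange(.data$person_id, .data$start_day) |>
    group_by(.data$person_id) |>
    mutate(
      next_state = lead(.data$state),
      adjacent = lead(.data$start_day) == .data$end_day
    ) |>
    ungroup() |>
    mutate(
      entry = .data$start_day - .data$index_day,
      exit = .data$end_day - .data$index_day
    ) |>
    filter(.data$state == ft[["from"]], .data$exit > 0L, .data$entry < horizon) |>
    mutate(
      event = as.integer(
        !is.na(.data$next_state) & .data$adjacent &
          .data$next_state == ft[["to"]] & .data$exit <= horizon
      ),
      entry = pmax(.data$entry, 0L),
      exit = pmin(.data$exit, as.integer(horizon))
    ) |>
    filter(.data$exit > .data$entry) |>
    select("person_id", "entry", "exit", "event")
  out <- inner_join(sojourns, select(cohort, "person_id", all_of(covs)),
    by = "person_id"
  )
  structure(out, class = c("risk_set", class(out)), edge = edge, horizon = horizon)
}

#' Fit a Cox proportional hazards model for one transition
#'
#' Maximises the Cox partial likelihood under left truncation with Breslow
#' tie handling, and retains the Breslow baseline cumulative hazard at the
#' reference covariate pattern as a step function over follow-up days.
#' Covariate dummy columns without variation in the risk set are dropped
#' from the design (and recorded) so the fit proceeds on the remainder.
#'
#' @param data A `risk_set` from [build_risk_sets()].
#' @param edge Transition label (defaults to the risk set's attribute).
#' @param horizon Follow-up length (defaults to the risk set's attribute).
#' @return Object of class `transition_cox`: coefficients with standard
#'   errors, baseline cumulative-hazard increments keyed by event day, event
#'   counts and dropped terms.
#' @export
fit_transition_cox <- function(data, edge = attr(data, "edge"),
                               horizon = attr(data, "horizon") %||% 365L) {
  assert_columns(data, c("entry", "exit", "event"), "risk set")
  n_events <- sum(data$event)
  if (n_events == 0L) {
    abort(paste0(
      "no events for transition ", edge %||% "?",
      ": exclude this edge from the transition set"
    ))
  }
  X <- covariate_design(data)
  keep <- apply(X, 2L, function(col) length(unique(col)) > 1L)
  dropped <- colnames(X)[!keep]
  X <- X[, keep, drop = FALSE]

  # with very few events some coefficients have a monotone partial
  # likelihood (estimate drifts to +-Inf with matching huge SE); the flag is
  # recorded instead of surfacing the optimiser's warning on every rare
  # edge. Terms whose estimate comes back non-finite (singular or fully
  # separated sparse dummies) are dropped and the model refitted.
  monotone <- FALSE
  for (attempt in 1:8) {
    df <- as_tibble(X, .name_repair = "minimal")
    safe <- paste0("x", seq_len(ncol(X)), recycle0 = TRUE)
    names(df) <- safe
    df$entry <- data$entry
    df$exit <- data$exit
    df$event <- data$event
    rhs <- if (length(safe) > 0L) paste(safe, collapse = " + ") else "1"
    f <- stats::as.formula(
      paste("survival::Surv(entry, exit, event) ~", rhs)
    )
    fit <- withCallingHandlers(
      survival::coxph(f, data = df, ties = "breslow", x = FALSE, y = FALSE),
      warning = function(w) {
        if (grepl("beta may be infinite|did not converge|coefficient may be infinite",
          conditionMessage(w)
        )) {
          monotone <<- TRUE
          invokeRestart("muffleWarning")
        }
      }
    )
    est <- coef(fit) %||% numeric(0)
    bad <- !is.finite(est)
    if (!any(bad)) break
    if (attempt == 8L) {
      abort(paste0(
        "Cox fit for ", edge, " did not converge to finite estimates for: ",
        paste(colnames(X)[bad], collapse = ", ")
      ))
    }
    warn(paste0(
      "transition ", edge, ": non-finite estimate(s) for ",
      paste(colnames(X)[bad], collapse = ", "), "; term(s) dropped"
    ))
    dropped <- c(dropped, colnames(X)[bad])
    X <- X[, !bad, drop = FALSE]
  }
  se <- if (length(est) > 0L) sqrt(diag(as.matrix(vcov(fit)))) else numeric(0)
  coefs <- tibble(
    term = colnames(X),
    estimate = unname(est),
    std_error = unname(se)
  )

  bh <- survival::basehaz(fit, centered = FALSE)
  inc <- diff(c(0, bh$hazard))
  # infinite coefficients (monotone likelihood on rare edges) can push the
  # reference-pattern baseline to 0/NaN at some steps; keep the finite jumps
  nz <- is.finite(inc) & inc > 0
  base <- tibble(time = as.integer(bh$time[nz]), increment = inc[nz])
  inc_vec <- numeric(horizon)
  ok <- base$time >= 1L & base$time <= horizon
  inc_vec[base$time[ok]] <- base$increment[ok]

  structure(
    list(
      edge = edge, coefficients = coefs, basehaz = base, inc_vec = inc_vec,
      dropped_terms = dropped, n = nrow(data), n_events = n_events,
      horizon = as.integer(horizon), loglik = fit$loglik,
      monotone_likelihood = monotone
    ),
    class = "transition_cox"
  )
}

#' @export
print.transition_cox <- function(x, ...) {
  cat("<transition_cox> ", x$edge, ": ", x$n_events, " events / ",
    x$n, " sojourns\n",
    sep = ""
  )
  print(x$coefficients, n = 5)
  if (length(x$dropped_terms) > 0L) {
    cat("  dropped (no variation):", paste(x$dropped_terms, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Predict the daily baseline-hazard increment for covariate patterns
#'
#' Returns `dLambda0(t) * exp(x'beta)`: the jump of the fitted cumulative
#' hazard over the day step from `t` to `t + 1` (events recorded at exit day
#' `t + 1`), scaled by the covariate pattern's hazard ratio. Zero beyond the
#' last observed event day.
#'
#' @param model A `transition_cox`.
#' @param newdata Tibble of covariate patterns (schema columns).
#' @param t Day, `0 <= t < horizon`.
#' @return Numeric vector of nonnegative increments, one per row of
#'   `newdata`.
#' @export
predict_daily_increment <- function(model, newdata, t) {
  stopifnot(length(t) == 1L)
  if (t < 0 || t >= model$horizon) abort("t must be in [0, horizon)")
  base <- model$inc_vec[[t + 1L]]
  base * exp(linear_predictor(model, newdata))
}

linear_predictor <- function(model, newdata) {
  X <- covariate_design(newdata)
  beta <- setNames(model$coefficients$estimate, model$coefficients$term)
  as.vector(X[, names(beta), drop = FALSE] %*% beta)
}

#' Fit Cox models for all transitions
#'
#' Builds the risk set and fits [fit_transition_cox()] for each of the 20
#' legal edges. Edges with zero observed events are dropped from the
#' transition set with a warning (the discrete event simulation then treats
#' their hazard as zero).
#'
#' @inheritParams build_risk_sets
#' @param edges Tibble of edges to fit (default all 20).
#' @return Object of class `transition_model_set`.
#' @export
fit_transition_models <- function(timeline, cohort, horizon = 365L,
                                  edges = lts_transitions()) {
  models <- list()
  dropped_edges <- character(0)
  for (edge in edges$edge) {
    rs <- build_risk_sets(timeline, cohort, edge, horizon)
    if (sum(rs$event) == 0L) {
      warn(paste0("no events for transition ", edge, "; edge dropped"))
      dropped_edges <- c(dropped_edges, edge)
      next
    }
    models[[edge]] <- fit_transition_cox(rs, edge, horizon)
  }
  structure(
    list(
      models = models, dropped_edges = dropped_edges,
      horizon = as.integer(horizon)
    ),
    class = "transition_model_set"
  )
}

#' @export
print.transition_model_set <- function(x, ...) {
  cat("<transition_model_set>", length(x$models), "fitted transitions")
  if (length(x$dropped_edges) > 0L) {
    cat(";", length(x$dropped_edges), "dropped:", paste(x$dropped_edges, collapse = ", "))
  }
  cat("\n")
  ev <- map_int(x$models, "n_events")
  cat("  events per edge:", paste0(names(ev), "=", ev, collapse = ", "), "\n")
  invisible(x)
}

#' Write a fitted transition set as CSV files
#'
#' `coefficients.csv` holds one row per (edge, covariate level) with the
#' hazard ratio and 95% confidence interval; `baseline_hazards.csv` holds
#' the Breslow baseline cumulative-hazard increments per (edge, day).
#'
#' @param x A `transition_model_set`.
#' @param dir Output directory.
#' @return `x` invisibly.
#' @export
write_transition_models <- function(x, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_csv(tidy(x), file.path(dir, "coefficients.csv"))
  base <- purrr::map_dfr(
    x$models,
    function(m) mutate(m$basehaz, edge = m$edge, .before = 1L)
  )
  readr::write_csv(base, file.path(dir, "baseline_hazards.csv"))
  invisible(x)
}
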