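# broom-style tidiers for the fitted objects.

# split a dummy term like "prior_unemptwo_plus" into covariate + level
parse_terms <- function(terms) {
  covs <- names(covariate_schema())
  covs <- covs[order(nchar(covs), decreasing = TRUE)] # longest prefix wins
  variable <- rep(NA_character_, length(terms))
  level <- rep(NA_character_, length(terms))
  for (cv in covs) {
    hit <- is.na(variable) & startsWith(terms, cv)
    variable[hit] <- cv
    level[hit] <- substring(terms[hit], nchar(cv) + 1L)
  }
  tibble(variable = variable, level = level)
}

#' Tidy a per-transition Cox fit
#'
#' One row per covariate level with the hazard ratio and Wald 95%
#' confidence interval.
#'
#' @param x A `transition_cox`.
#' @param exponentiate Report hazard ratios (default) or log hazard ratios.
#' @param ... Unused.
#' @return Tibble `edge`, `variable`, `level`, `term`, `estimate`,
#'   `std_error`, `hr` (or `estimate` only), `conf_low`, `conf_high`,
#'   `p_value`.
#' @export
tidy.transition_cox <- function(x, exponentiate = TRUE, ...) {
  z <- qnorm(0.975)
  out <- x$coefficients |>
    mutate(
      statistic = .data$estimate / .data$std_error,
      p_value = 2 * stats::pnorm(-abs(.data$statistic)),
      conf_low = .data$estimate - z * .data$std_error,
      conf_high = .data$estimate + z * .data$std_error
    )
  if (exponentiate) {
    out <- mutate(out,
      estimate = exp(.data$estimate),
      conf_low = exp(.data$conf_low), conf_high = exp(.data$conf_high)
    )
  }
  bind_cols(
    tibble(edge = rep(x$edge %||% NA_character_, nrow(out))),
    parse_terms(out$term), out
  )
}

#' @export
glance.transition_cox <- function(x, ...) {
  tibble(
    edge = x$edge %||% NA_character_, n_sojourns = x$n, n_events = x$n_events,
    n_terms = nrow(x$coefficients), n_dropped = length(x$dropped_terms),
    loglik = x$loglik[[length(x$loglik)]]
  )
}

#' @export
tidy.transition_model_set <- function(x, exponentiate = TRUE, ...) {
  purrr::map_dfr(x$models, tidy, exponentiate = exponentiate)
}

#' @export
glance.transition_model_set <- function(x, ...) {
  purrr::map_dfr(x$models, glance)
}

#' Tidy a per-outcome logistic fit
#'
#' Odds ratios with Wald 95% confidence intervals and per-level p-values,
#' one row per covariate level (plus the intercept).
#'
#' @param x An `outcome_logistic`.
#' @param exponentiate Report odds ratios (default) or log odds.
#' @param ... Unused.
#' @export
tidy.outcome_logistic <- function(x, exponentiate = TRUE, ...) {
  s <- summary(x$fit)$coefficients
  z <- qnorm(0.975)
  out <- tibble(
    term = rownames(s),
    estimate = s[, "Estimate"],
    std_error = s[, "Std. Error"],
    statistic = s[, "z value"],
    p_value = s[, "Pr(>|z|)"],
    conf_low = s[, "Estimate"] - z * s[, "Std. Error"],
    conf_high = s[, "Estimate"] + z * s[, "Std. Error"]
  )
  if (exponentiate) {
    out <- mutate(out,
      estimate = exp(.data$estimate),
      conf_low = exp(.data$conf_low), conf_high = exp(.data$conf_high)
    )
  }
  parsed <- parse_terms(out$term)
  parsed$variable[out$term == "(Intercept)"] <- "(Intercept)"
  bind_cols(
    tibble(outcome = rep(x$outcome_state, nrow(out))),
    parsed, out
  )
}

#' @export
glance.outcome_logistic <- function(x, ...) {
  tibble(
    outcome = x$outcome_state, n = x$n, n_cases = x$n_cases,
    prevalence = x$n_cases / x$n,
    deviance = x$fit$deviance, aic = x$fit$aic,
    n_merged_levels = sum(map_int(
      x$level_map,
      function(m) sum(m != names(m))
    ))
  )
}

#' @export
tidy.outcome_logistic_set <- function(x, exponentiate = TRUE, ...) {
  purrr::map_dfr(x$models, tidy, exponentiate = exponentiate)
}

#' @export
glance.outcome_logistic_set <- function(x, ...) {
  purrr::map_dfr(x$models, glance)
}

#' @export
tidy.lts_roc <- function(x, ...) {
  x$curve
}

#' @export
glance.lts_roc <- function(x, ...) {
  tibble(
    auc = x$auc, auc_class = classify_auc(x$auc),
    n_cases = x$n_cases, n_controls = x$n_controls
  )
}

#' @export
tidy.lts_experiment <- function(x, ...) {
  x$report
}

#' @export
glance.lts_experiment <- function(x, ...) {
  purrr::map_dfr(x$scenarios, function(s) {
    tibble(
      scenario = s$label,
      n_generated = s$counts$n[s$counts$stage == "generated"],
      n_included = s$counts$n[s$counts$stage == "eligible_lts"],
      n_train = s$counts$n[s$counts$stage == "training"],
      n_valid = s$counts$n[s$counts$stage == "validation"],
      n_edges_fitted = length(s$cox$models)
    )
  })
}
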