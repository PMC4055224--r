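# The comparison predictor: one additive binary logistic regression per
# outcome state, fitted on non-censored training rows. Six separate binary
# models (not one multinomial fit), so a person's six predicted
# probabilities need not sum to 1 -- that is a property of the design, not a
# bug, and is asserted nowhere.

#' Fit the logistic regression for one outcome state
#'
#' Maximum-likelihood fit of the indicator "state at day 365 equals
#' `outcome_state`" on the dummy-coded covariates in additive form. Rows
#' with censored outcome are excluded. The rare socio-economic category
#' `unregistered` is merged into `without_job` when it carries zero cases
#' (with a warning); covariate levels with no rows at all are dropped from
#' the design.
#'
#' @param cohort Cohort tibble from [assemble_cohort()] (training part).
#' @param outcome_state One of the six state labels.
#' @param covariates Which covariates to include (default all seven; used by
#'   [variable_importance()] to refit without one variable).
#' @return Object of class `outcome_logistic`.
#' @export
fit_outcome_logistic <- function(cohort, outcome_state,
                                 covariates = names(covariate_schema())) {
  if (!outcome_state %in% lts_states()) {
    abort(paste0("unknown outcome state: ", outcome_state))
  }
  schema <- covariate_schema()
  covariates <- intersect(names(schema), covariates)
  data <- filter(cohort, .data$outcome != "censored")
  data <- as_covariate_factors(data, schema, covariates)
  y <- as.integer(data$outcome == outcome_state)
  if (sum(y) == 0L || sum(y) == length(y)) {
    abort(paste0(
      "cannot fit outcome ", outcome_state,
      ": need at least one case and one non-case among non-censored rows"
    ))
  }

  # Pure levels (zero cases or all cases) make the level's log odds
  # infinite. A covariate whose observed levels are *all* pure separates the
  # outcome on its own: that is complete separation and an error. An
  # individually pure level in an otherwise mixed covariate is merged into
  # the reference level (the rare socio-economic `unregistered` category
  # goes into `without_job`) with a warning, mirroring how sparse register
  # categories are reported.
  level_map <- list()
  for (nm in covariates) {
    rate <- tapply(y, data[[nm]], mean)
    count <- tapply(y, data[[nm]], length)
    seen <- !is.na(rate) & count > 0L
    if (sum(seen) > 1L && all(rate[seen] %in% c(0, 1))) {
      abort(paste0(
        "complete separation for outcome ", outcome_state,
        ": covariate `", nm, "` perfectly classifies the outcome"
      ))
    }
    ref <- levels(data[[nm]])[[1L]]
    target <- if (nm == "socio_economic") "without_job" else ref
    pure <- setdiff(names(rate)[seen & rate %in% c(0, 1)], c(ref, target))
    unseen <- setdiff(names(rate)[!seen], c(ref, target))
    map <- setNames(levels(data[[nm]]), levels(data[[nm]]))
    if (length(pure) > 0L) {
      warn(paste0(
        "outcome ", outcome_state, ": level(s) ",
        paste0(nm, "=", pure, collapse = ", "),
        " carry no outcome variation; merged into `", target, "`"
      ))
    }
    if (length(c(pure, unseen)) > 0L) {
      map[c(pure, unseen)] <- target
      data[[nm]] <- factor(unname(map[as.character(data[[nm]])]),
        levels = unique(unname(map))
      )
    }
    level_map[[nm]] <- map
  }
  for (nm in covariates) data[[nm]] <- droplevels(data[[nm]])

  df <- data[, covariates, drop = FALSE]
  df$.y <- y
  use <- covariates[map_int(df[covariates], function(col) length(unique(col))) > 1L]
  separation <- FALSE
  rhs <- if (length(use) > 0L) use else "1"
  fit <- withCallingHandlers(
    glm(reformulate(rhs, response = ".y"),
      data = df, family = binomial(),
      control = list(maxit = 100L)
    ),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w))) {
        separation <<- TRUE
        invokeRestart("muffleWarning")
      }
    }
  )
  est <- coef(fit)
  if (any(is.na(est))) {
    abort(paste0(
      "collinear design for outcome ", outcome_state, ": ",
      paste(names(est)[is.na(est)], collapse = ", ")
    ))
  }
  if (separation && !fit$converged) {
    abort(paste0(
      "complete separation for outcome ", outcome_state, " on: ",
      paste(names(est)[-1L][abs(est[-1L]) > 10], collapse = ", ")
    ))
  }
  if (separation) {
    warn(paste0(
      "outcome ", outcome_state,
      ": some fitted probabilities are numerically 0 or 1 (sparse cells)"
    ))
  }

  structure(
    list(
      outcome_state = outcome_state, fit = fit, covariates = covariates,
      fitted_covariates = use, level_map = level_map,
      n = length(y), n_cases = sum(y)
    ),
    class = "outcome_logistic"
  )
}

#' @export
print.outcome_logistic <- function(x, ...) {
  cat("<outcome_logistic> outcome ", x$outcome_state, ": ", x$n_cases,
    " cases / ", x$n, " persons\n",
    sep = ""
  )
  invisible(x)
}

#' Predicted probability of one outcome state
#'
#' Inverse-logit evaluation of the fitted linear predictor; applies the same
#' `unregistered -> without_job` merge the fit used. Unknown covariate
#' levels are an error.
#'
#' @param model An `outcome_logistic`.
#' @param newdata Tibble with the model's covariate columns.
#' @return Numeric vector of probabilities in (0, 1).
#' @export
predict_probability <- function(model, newdata) {
  schema <- covariate_schema()
  newdata <- as_covariate_factors(newdata, schema, model$covariates)
  for (nm in model$fitted_covariates) {
    map <- model$level_map[[nm]]
    recoded <- unname(map[as.character(newdata[[nm]])])
    kept <- levels(model$fit$model[[nm]])
    bad <- setdiff(unique(recoded), kept)
    if (length(bad) > 0L) {
      abort(paste0(
        "covariate level(s) unknown to the ", model$outcome_state,
        " model: ", nm, " = ", paste(bad, collapse = ", ")
      ))
    }
    newdata[[nm]] <- factor(recoded, levels = kept)
  }
  unname(predict(model$fit, newdata = newdata, type = "response"))
}

#' Fit all six per-outcome logistic models
#'
#' @inheritParams fit_outcome_logistic
#' @return Object of class `outcome_logistic_set` (named list of fits).
#' @export
fit_outcome_logistics <- function(cohort,
                                  covariates = names(covariate_schema())) {
  fits <- map(
    setNames(lts_states(), lts_states()),
    function(st) fit_outcome_logistic(cohort, st, covariates)
  )
  structure(list(models = fits), class = "outcome_logistic_set")
}

#' Predicted probabilities for all six outcome states
#'
#' Six separate binary predictions; the per-person probabilities are not
#' constrained to sum to 1.
#'
#' @param set An `outcome_logistic_set`.
#' @param newdata Cohort-like tibble with `person_id` and covariates.
#' @return Tibble `person_id`, `source = "logistic"`, and `P_<state>`
#'   columns.
#' @export
predict_outcome_probabilities <- function(set, newdata) {
  out <- tibble(person_id = newdata$person_id, source = "logistic")
  for (st in lts_states()) {
    out[[paste0("P_", st)]] <- predict_probability(set$models[[st]], newdata)
  }
  out
}

#' Variable-wise Wald tests
#'
#' Joint Wald chi-square test per covariate (all its dummy levels at once),
#' the variable-level analogue of the per-level z tests.
#'
#' @param model An `outcome_logistic`.
#' @return Tibble `variable`, `chisq`, `df`, `p_value`.
#' @export
variable_wald_tests <- function(model) {
  est <- coef(model$fit)
  V <- vcov(model$fit)
  asg <- attr(model.matrix(model$fit), "assign")
  labs <- attr(terms(model$fit), "term.labels")
  purrr::map_dfr(seq_along(labs), function(j) {
    idx <- which(asg == j)
    b <- est[idx]
    W <- as.numeric(t(b) %*% solve(V[idx, idx, drop = FALSE]) %*% b)
    tibble(
      variable = labs[[j]], chisq = W, df = length(idx),
      p_value = pchisq(W, df = length(idx), lower.tail = FALSE)
    )
  })
}
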