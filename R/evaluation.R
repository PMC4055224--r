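# Validation-set scoring: per-person Brier scores, the covariate-free null
# benchmark, tie-corrected ROC/AUC with the conventional discrimination
# bands, leave-one-variable-out importance, and the summary report.

#' Brier scores
#'
#' Per-person squared difference between the binary outcome and the
#' predicted probability, `(y_i - p_i)^2`, and their mean. A constant
#' prediction equal to the outcome prevalence yields mean `p * (1 - p)`.
#'
#' @param predictions Probabilities in `[0, 1]`.
#' @param outcomes Binary outcomes (0/1 or logical), same length.
#' @return List with `scores` (numeric vector) and `mean`.
#' @export
#' @examples
#' brier_score(rep(0.662, 10), rep(c(1, 0), c(7, 3)))$mean
brier_score <- function(predictions, outcomes) {
  outcomes <- as.numeric(outcomes)
  if (length(predictions) != length(outcomes)) {
    abort("predictions and outcomes must have the same length")
  }
  if (any(predictions < 0 | predictions > 1, na.rm = TRUE)) {
    abort("predictions must be probabilities in [0, 1]")
  }
  if (!all(outcomes %in% c(0, 1))) abort("outcomes must be binary")
  scores <- (outcomes - predictions)^2
  list(scores = scores, mean = mean(scores))
}

#' Null-model Brier score
#'
#' Mean Brier score of the covariate-free model that predicts the training
#' prevalence for every person: `q * (1 - p)^2 + (1 - q) * p^2` where `p` is
#' the constant prediction and `q` the validation prevalence.
#'
#' @param training_prevalence Constant predicted probability in `[0, 1]`.
#' @param validation_outcomes Binary outcomes of the validation persons.
#' @return Mean Brier score (single number).
#' @export
null_model_brier <- function(training_prevalence, validation_outcomes) {
  stopifnot(length(training_prevalence) == 1L)
  if (training_prevalence < 0 || training_prevalence > 1) {
    abort("training_prevalence must be in [0, 1]")
  }
  brier_score(
    rep(training_prevalence, length(validation_outcomes)),
    validation_outcomes
  )$mean
}

#' ROC curve and tie-corrected AUC
#'
#' AUC by the rank (Mann-Whitney) statistic counting tied predictions as
#' 1/2, equivalent to the trapezoidal area under the ROC curve over all
#' distinct thresholds. A constant predictor scores exactly 0.5.
#'
#' @param predictions Numeric risk scores (any monotone scale).
#' @param outcomes Binary outcomes; both classes must be present.
#' @return Object of class `lts_roc`: `auc`, `curve` (tibble `threshold`,
#'   `fpr`, `tpr` from (0,0) to (1,1)), `n_cases`, `n_controls`.
#' @export
roc_auc <- function(predictions, outcomes) {
  outcomes <- as.numeric(outcomes)
  if (length(predictions) != length(outcomes)) {
    abort("predictions and outcomes must have the same length")
  }
  if (!all(outcomes %in% c(0, 1))) abort("outcomes must be binary")
  n1 <- sum(outcomes == 1)
  n0 <- sum(outcomes == 0)
  if (n1 == 0L || n0 == 0L) {
    abort("both classes must be present to compute a ROC curve")
  }
  r <- rank(predictions, ties.method = "average")
  auc <- (sum(r[outcomes == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)

  ord <- order(predictions, decreasing = TRUE)
  y <- outcomes[ord]
  p <- predictions[ord]
  last_of_tie <- c(p[-1] != p[-length(p)], TRUE)
  curve <- tibble(
    threshold = c(Inf, p[last_of_tie]),
    tpr = c(0, cumsum(y)[last_of_tie] / n1),
    fpr = c(0, cumsum(1 - y)[last_of_tie] / n0)
  )
  structure(
    list(auc = auc, curve = curve, n_cases = n1, n_controls = n0),
    class = "lts_roc"
  )
}

#' @export
print.lts_roc <- function(x, ...) {
  cat("<lts_roc> AUC = ", format(round(x$auc, 4)), " (", classify_auc(x$auc),
    "); ", x$n_cases, " cases / ", x$n_controls, " controls\n",
    sep = ""
  )
  invisible(x)
}

#' Discrimination band of an AUC
#'
#' The conventional rough guide: 0.9-1.0 excellent, 0.8-0.9 good, 0.7-0.8
#' fair, 0.6-0.7 poor, below 0.6 fail. Intervals are closed on the left
#' (an AUC of exactly 0.8 is "good").
#'
#' @param auc Numeric vector of AUC values in `[0, 1]`.
#' @return Character vector of band labels.
#' @export
#' @examples
#' classify_auc(c(0.59, 0.60, 0.72, 0.95))
classify_auc <- function(auc) {
  if (any(auc < 0 | auc > 1, na.rm = TRUE)) abort("auc must be in [0, 1]")
  labels <- c("fail", "poor", "fair", "good", "excellent")
  labels[findInterval(auc, c(0.6, 0.7, 0.8, 0.9)) + 1L]
}

#' Leave-one-variable-out importance
#'
#' Refits the outcome's logistic model without each variable in turn and
#' measures the relative change in validation accuracy:
#' `delta_auc_pct = 100 * (AUC_full - AUC_reduced) / AUC_full` and
#' `delta_brier_pct = 100 * (Brier_reduced - Brier_full) / Brier_full`, so
#' positive values mean accuracy is lost when the variable is removed.
#'
#' @param cohort_train,cohort_valid Training and validation cohort tibbles.
#' @param outcome_state Outcome to score (e.g. `"W"`).
#' @param variables Variables to knock out (default all seven).
#' @return Tibble `variable`, `auc_full`, `auc_reduced`, `delta_auc_pct`,
#'   `brier_full`, `brier_reduced`, `delta_brier_pct`.
#' @export
variable_importance <- function(cohort_train, cohort_valid, outcome_state,
                                variables = names(covariate_schema())) {
  valid <- filter(cohort_valid, .data$outcome != "censored")
  y <- as.integer(valid$outcome == outcome_state)
  full <- fit_outcome_logistic(cohort_train, outcome_state)
  p_full <- predict_probability(full, valid)
  auc_full <- roc_auc(p_full, y)$auc
  brier_full <- brier_score(p_full, y)$mean
  purrr::map_dfr(variables, function(v) {
    red <- fit_outcome_logistic(
      cohort_train, outcome_state,
      covariates = setdiff(names(covariate_schema()), v)
    )
    p_red <- predict_probability(red, valid)
    auc_red <- roc_auc(p_red, y)$auc
    brier_red <- brier_score(p_red, y)$mean
    tibble(
      variable = v,
      auc_full = auc_full, auc_reduced = auc_red,
      delta_auc_pct = 100 * (auc_full - auc_red) / auc_full,
      brier_full = brier_full, brier_reduced = brier_red,
      delta_brier_pct = 100 * (brier_red - brier_full) / brier_full
    )
  })
}

#' Summary report over states and methods
#'
#' One row per (state, method) with the predicted prevalence (mean predicted
#' probability over non-censored validation persons; training prevalence for
#' the null rows), the observed validation prevalence, AUC (in percent, with
#' its discrimination band; exactly 50% for the null rows by the tie
#' correction) and the mean Brier score. Censored validation persons are
#' excluded from every metric.
#'
#' @param cohort_train Training cohort (supplies null prevalences).
#' @param cohort_valid Validation cohort (supplies outcomes).
#' @param predictions Prediction tibble with `person_id`, `source`
#'   (`"logistic"` and/or `"DES"`) and `P_<state>` columns, e.g. rows from
#'   [predict_outcome_probabilities()] and [predict_state_occupation()].
#' @return Tibble `state`, `method`, `prevalence_pct`, `observed_pct`,
#'   `auc_pct`, `auc_class`, `brier`.
#' @export
build_report <- function(cohort_train, cohort_valid, predictions) {
  train <- filter(cohort_train, .data$outcome != "censored")
  valid <- filter(cohort_valid, .data$outcome != "censored")
  methods <- unique(predictions$source)
  if (!all(c("logistic", "DES") %in% methods)) {
    abort("predictions must contain both 'logistic' and 'DES' rows")
  }
  safe_auc <- function(p, y, st, m) {
    if (sum(y) == 0L || sum(y) == length(y)) {
      warn(paste0(
        "state ", st, " has a single outcome class in validation; ",
        m, " AUC reported as NA"
      ))
      return(NA_real_)
    }
    roc_auc(p, y)$auc
  }
  rows <- list()
  for (st in lts_states()) {
    y <- as.integer(valid$outcome == st)
    p_tr <- mean(train$outcome == st)
    rows[[length(rows) + 1L]] <- tibble(
      state = st, method = "null",
      prevalence_pct = 100 * p_tr,
      observed_pct = 100 * mean(y),
      auc_pct = 100 * safe_auc(rep(p_tr, length(y)), y, st, "null"),
      brier = null_model_brier(p_tr, y)
    )
    for (m in c("logistic", "DES")) {
      pr <- predictions |>
        filter(.data$source == m) |>
        inner_join(select(valid, "person_id"), by = "person_id")
      if (nrow(pr) != nrow(valid)) {
        abort(paste0("missing ", m, " predictions for some validation persons"))
      }
      pr <- pr[match(valid$person_id, pr$person_id), ]
      p <- pr[[paste0("P_", st)]]
      rows[[length(rows) + 1L]] <- tibble(
        state = st, method = m,
        prevalence_pct = 100 * mean(p),
        observed_pct = 100 * mean(y),
        auc_pct = 100 * safe_auc(p, y, st, m),
        brier = brier_score(p, y)$mean
      )
    }
  }
  bind_rows(rows) |>
    mutate(auc_class = classify_auc(.data$auc_pct / 100), .after = "auc_pct")
}
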