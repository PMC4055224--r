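# ggplot2 methods for the result objects.

#' Plot a ROC curve
#'
#' @param object An `lts_roc` from [roc_auc()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.lts_roc <- function(object, ...) {
  ggplot2::ggplot(object$curve, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed", colour = "grey60") +
    ggplot2::geom_step() +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "False positive rate (1 - specificity)",
      y = "True positive rate (sensitivity)",
      title = sprintf("ROC curve (AUC = %.3f, %s)", object$auc, classify_auc(object$auc))
    )
}

#' Plot baseline cumulative hazards of a fitted transition set
#'
#' Step curves of the Breslow baseline cumulative hazard per transition.
#'
#' @param object A `transition_model_set`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.transition_model_set <- function(object, ...) {
  df <- purrr::map_dfr(object$models, function(m) {
    tibble(
      edge = m$edge, time = c(0, m$basehaz$time),
      cumhaz = cumsum(c(0, m$basehaz$increment))
    )
  })
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$cumhaz)) +
    ggplot2::geom_step() +
    ggplot2::facet_wrap(~edge, scales = "free_y") +
    ggplot2::labs(
      x = "Days since initial sick-listing",
      y = "Baseline cumulative hazard"
    )
}

#' Plot an experiment report
#'
#' Dot plot of AUC per state and method, faceted by scenario.
#'
#' @param object An `lts_experiment`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.lts_experiment <- function(object, ...) {
  ggplot2::ggplot(
    object$report,
    ggplot2::aes(x = .data$state, y = .data$auc_pct, colour = .data$method)
  ) +
    ggplot2::geom_hline(yintercept = 50, linetype = "dashed", colour = "grey60") +
    ggplot2::geom_point(position = ggplot2::position_dodge(width = 0.4), size = 2) +
    ggplot2::facet_wrap(~scenario) +
    ggplot2::labs(
      x = "One-year outcome state", y = "AUC (%)", colour = "Method"
    )
}

#' Plot predicted state-occupation probabilities
#'
#' Stacked per-person probabilities over the six states for a prediction
#' matrix (DES or logistic source).
#'
#' @param predictions Tibble with `person_id` and `P_<state>` columns.
#' @param max_persons Cap on persons shown (default 50).
#' @return A ggplot object.
#' @export
plot_state_occupation <- function(predictions, max_persons = 50L) {
  df <- predictions |>
    slice_head(n = max_persons) |>
    tidyr::pivot_longer(
      cols = dplyr::starts_with("P_"),
      names_to = "state", names_prefix = "P_", values_to = "probability"
    ) |>
    mutate(state = factor(.data$state, levels = lts_states()))
  ggplot2::ggplot(df, ggplot2::aes(
    x = factor(.data$person_id),
    y = .data$probability, fill = .data$state
  )) +
    ggplot2::geom_col() +
    ggplot2::labs(
      x = "Person", y = "P(state at day 365)", fill = "State"
    ) +
    ggplot2::theme(axis.text.x = ggplot2::element_blank())
}
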