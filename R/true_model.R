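#' Ground-truth multi-state hazard model
#'
#' A generating model for the synthetic cohort: one nonnegative baseline
#' daily hazard per legal transition (constant or piecewise-constant over
#' day intervals), optional log hazard ratios per dummy-coded covariate
#' level, and a daily censoring hazard collapsing age-60 / emigration /
#' death into one right-truncation rate.
#'
#' @param baseline Named list over (a subset of) the 20 edges of
#'   [lts_transitions()]. Each element is either a single nonnegative daily
#'   rate or a data frame with columns `from_day` and `rate` describing a
#'   piecewise-constant rate (left-closed intervals starting at `from_day`,
#'   first `from_day` must be 0). Omitted edges get rate 0.
#' @param hazard_ratios Named list over edges; each element a named numeric
#'   vector of log hazard ratios keyed by dummy-coded covariate terms (see
#'   `schema_terms`), e.g. `c(genderMale = 0.2)`. Terms not listed are 0.
#' @param censor_hazard Single nonnegative daily censoring rate.
#' @param schema Covariate schema the hazard-ratio terms must belong to.
#'
#' @return An object of class `true_model`.
#' @export
#' @examples
#' toy <- true_model(
#'   baseline = list("LTS->W" = 0.01, "LTS->D" = 0.001),
#'   hazard_ratios = list("LTS->W" = c(gendermale = 0.3))
#' )
true_model <- function(baseline, hazard_ratios = list(), censor_hazard = 0,
                       schema = covariate_schema()) {
  edges <- lts_transitions()$edge
  bad <- setdiff(names(baseline), edges)
  if (length(bad) > 0L) {
    abort(paste0("baseline names are not legal edges: ", paste(bad, collapse = ", ")))
  }
  baseline <- map(baseline, function(b) {
    if (is.data.frame(b)) {
      assert_columns(b, c("from_day", "rate"), "piecewise baseline")
      if (b$from_day[[1]] != 0 || is.unsorted(b$from_day, strictly = TRUE)) {
        abort("piecewise baseline `from_day` must start at 0 and increase")
      }
      if (any(b$rate < 0)) abort("baseline hazards must be >= 0")
      b
    } else {
      if (length(b) != 1L || b < 0) abort("baseline hazards must be single rates >= 0")
      tibble(from_day = 0, rate = as.numeric(b))
    }
  })
  terms <- tolower(schema_terms(schema))
  for (edge in names(hazard_ratios)) {
    if (!is_legal_edge(edge)) {
      abort(paste0("hazard_ratios edge is not legal: ", edge))
    }
    nm <- tolower(names(hazard_ratios[[edge]]))
    bad <- setdiff(nm, terms)
    if (length(bad) > 0L) {
      abort(paste0(
        "hazard_ratios for ", edge, " reference unknown covariate term(s): ",
        paste(bad, collapse = ", ")
      ))
    }
  }
  if (length(censor_hazard) != 1L || censor_hazard < 0) {
    abort("censor_hazard must be a single rate >= 0")
  }
  structure(
    list(
      baseline = baseline, hazard_ratios = hazard_ratios,
      censor_hazard = censor_hazard, schema = schema
    ),
    class = "true_model"
  )
}

# 20 x horizon matrix of baseline daily rates, rows keyed by edge.
baseline_rate_matrix <- function(model, horizon) {
  edges <- lts_transitions()$edge
  R <- matrix(0, nrow = length(edges), ncol = horizon, dimnames = list(edges, NULL))
  for (edge in names(model$baseline)) {
    b <- model$baseline[[edge]]
    t <- seq_len(horizon) - 1L
    R[edge, ] <- b$rate[findInterval(t, b$from_day)]
  }
  R
}

# n x 20 matrix of per-person hazard multipliers exp(X beta_edge).
hazard_multipliers <- function(model, covariates) {
  edges <- lts_transitions()$edge
  X <- covariate_design(covariates, model$schema)
  terms_lc <- tolower(colnames(X))
  M <- matrix(1, nrow = nrow(X), ncol = length(edges), dimnames = list(NULL, edges))
  for (edge in names(model$hazard_ratios)) {
    beta <- model$hazard_ratios[[edge]]
    idx <- match(tolower(names(beta)), terms_lc)
    M[, edge] <- exp(as.vector(X[, idx, drop = FALSE] %*% unname(beta)))
  }
  M
}

#' @export
print.true_model <- function(x, ...) {
  nz <- names(x$baseline)[map_dbl(x$baseline, function(b) max(b$rate)) > 0]
  cat("<true_model>\n")
  cat("  edges with positive baseline hazard:", length(nz), "of 20\n")
  cat("  edges with covariate effects:", length(x$hazard_ratios), "\n")
  cat("  daily censoring hazard:", format(x$censor_hazard), "\n")
  invisible(x)
}

#' Default generating models
#'
#' `true_model_growth()` is the package's reference generating model: exit
#' rates out of the initial sickness episode chosen so that roughly 4% of
#' persons are still in `LTS` after one year, a transition mix dominated by
#' moves between work, sickness absence and unemployment, rare transitions
#' into the absorbing disability state, and covariate effects planted on
#' return-to-work (male, middle age, self-employment favourable; joblessness,
#' chronic disease, prior sickness and especially prior unemployment
#' unfavourable), on unemployment entry (prior unemployment, joblessness)
#' and on disability (chronic disease, older age).
#' `true_model_recession()` shifts the same structure towards fewer
#' work returns, more unemployment and a steeper prior-unemployment
#' gradient. `true_model_null()` keeps the growth baselines but drops every
#' covariate effect, so no predictor carries information.
#'
#' @param censor_hazard Daily censoring rate (default 5e-5, about 1.8% of
#'   persons truncated within the follow-up year).
#' @return A `true_model` object.
#' @export
true_model_growth <- function(censor_hazard = 5e-5) {
  true_model(
    baseline = list(
      "LTS->W" = 0.0070, "LTS->U" = 0.0008, "LTS->TO" = 0.0016, "LTS->D" = 1e-4,
      "W->U" = 0.0012, "W->SA" = 0.0018, "W->TO" = 0.0004, "W->D" = 1e-5,
      "U->W" = 0.0120, "U->SA" = 0.0030, "U->TO" = 0.0008, "U->D" = 4e-5,
      "SA->W" = 0.0200, "SA->U" = 0.0030, "SA->TO" = 0.0070, "SA->D" = 2e-4,
      "TO->W" = 0.0100, "TO->U" = 0.0018, "TO->SA" = 0.0055, "TO->D" = 2e-5
    ),
    hazard_ratios = c(
      rep_work_effects(c(
        gendermale = 0.20, `age_group20-29` = -0.15, `age_group40-49` = 0.20,
        socio_economicself_employed = 0.25, socio_economicwithout_job = -0.45,
        job_typeother = -0.10, job_typeunregistered = -0.30,
        chronic_diseaseyes = -0.30, prior_saone_plus = -0.25,
        prior_unempone = -0.35, prior_unemptwo_plus = -0.65
      )),
      rep_edge_effects(
        c("LTS->U", "W->U", "SA->U", "TO->U"),
        c(
          prior_unempone = 0.50, prior_unemptwo_plus = 0.90,
          socio_economicwithout_job = 0.40
        )
      ),
      rep_edge_effects(
        c("LTS->D", "W->D", "U->D", "SA->D", "TO->D"),
        c(
          chronic_diseaseyes = 0.60, `age_group20-29` = -0.80,
          `age_group30-39` = -0.50, `age_group40-49` = -0.30
        )
      ),
      rep_edge_effects(
        c("W->SA", "U->SA", "TO->SA"),
        c(prior_saone_plus = 0.40)
      )
    ),
    censor_hazard = censor_hazard
  )
}

#' @rdname true_model_growth
#' @export
true_model_recession <- function(censor_hazard = 5e-5) {
  m <- true_model_growth(censor_hazard)
  m$baseline[["LTS->W"]]$rate <- 0.0060
  m$baseline[["W->U"]]$rate <- 0.0018
  m$baseline[["U->W"]]$rate <- 0.0100
  for (edge in c("LTS->W", "U->W", "SA->W", "TO->W")) {
    if (edge %in% names(m$hazard_ratios)) {
      hr <- m$hazard_ratios[[edge]]
      hr[["prior_unempone"]] <- -0.70
      hr[["prior_unemptwo_plus"]] <- -1.10
      hr[["gendermale"]] <- 0.08
      m$hazard_ratios[[edge]] <- hr
    }
  }
  m
}

#' @rdname true_model_growth
#' @export
true_model_null <- function(censor_hazard = 5e-5) {
  m <- true_model_growth(censor_hazard)
  m$hazard_ratios <- list()
  m
}

rep_work_effects <- function(beta) {
  rep_edge_effects(c("LTS->W", "U->W", "SA->W", "TO->W"), beta)
}

rep_edge_effects <- function(edges, beta) {
  setNames(rep(list(beta), length(edges)), edges)
}
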