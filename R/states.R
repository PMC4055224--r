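#' The six labour-market states
#'
#' State labels used throughout the package: `LTS` (the initial long-term
#' sickness episode of at least four weeks that defines cohort entry), `W`
#' (work, i.e. periods with no registered social benefit payment), `U`
#' (unemployment benefits), `SA` (recurrent sickness absence after the
#' initial episode has ended), `D` (disability pension, absorbing) and `TO`
#' (temporary out: maternity, education and similar benefits).
#'
#' @return Character vector of the six state labels.
#' @export
lts_states <- function() {
  c("LTS", "W", "U", "SA", "D", "TO")
}

#' The twenty legal transitions of the multi-state model
#'
#' Every non-absorbing state has four outgoing edges. `LTS` is entered only
#' at baseline (no edges back in), and `D` is absorbing (no edges out).
#' Recurrent sickness after leaving the initial episode is `SA`, never `LTS`
#' again.
#'
#' @return A tibble with columns `from`, `to` and `edge` (e.g. `"LTS->W"`),
#'   one row per legal transition, in a fixed canonical order.
#' @export
#' @examples
#' lts_transitions()
lts_transitions <- function() {
  tr <- tibble(
    from = rep(c("LTS", "W", "U", "SA", "TO"), each = 4L),
    to = c(
      "W", "U", "TO", "D",
      "U", "SA", "TO", "D",
      "W", "SA", "TO", "D",
      "W", "U", "TO", "D",
      "W", "U", "SA", "D"
    )
  )
  tr$edge <- edge_key(tr$from, tr$to)
  tr
}

is_legal_edge <- function(edge) {
  edge %in% lts_transitions()$edge
}

#' Baseline covariate schema
#'
#' The seven predictor variables recorded at the first day of the initial
#' sick-listing, with category levels. The first level of each covariate is
#' its reference level (female, age 50-59, wage earner,
#' sale/service/care-taking work, no chronic-disease insurance, no prior
#' sickness absence, no prior unemployment). `prior_sa` and `prior_unemp`
#' are derived from the 365 days preceding the index day; the other five are
#' baseline characteristics.
#'
#' @return Named list: covariate name -> character vector of levels,
#'   reference level first.
#' @export
covariate_schema <- function() {
  list(
    gender = c("female", "male"),
    age_group = c("50-59", "20-29", "30-39", "40-49"),
    socio_economic = c("wage_earner", "self_employed", "without_job", "unregistered"),
    job_type = c(
      "sale_service_care", "military", "management", "office",
      "farming_transport", "other", "unregistered"
    ),
    chronic_disease = c("no", "yes"),
    prior_sa = c("none", "one_plus"),
    prior_unemp = c("none", "one", "two_plus")
  )
}

# Dummy-coded column names implied by the schema (reference levels omitted),
# matching what model.matrix() produces on schema-ordered factors.
schema_terms <- function(schema = covariate_schema()) {
  unlist(imap(schema, function(levels, nm) paste0(nm, levels[-1])),
    use.names = FALSE
  )
}

# Coerce covariate columns to factors with schema level order; unknown
# category values are an error (prediction must never silently re-code).
as_covariate_factors <- function(data, schema = covariate_schema(),
                                 covariates = names(schema)) {
  assert_columns(data, covariates, "covariate table")
  for (nm in covariates) {
    x <- as.character(data[[nm]])
    bad <- setdiff(unique(x[!is.na(x)]), schema[[nm]])
    if (length(bad) > 0L) {
      abort(paste0(
        "unknown level(s) for covariate `", nm, "`: ",
        paste(bad, collapse = ", ")
      ))
    }
    data[[nm]] <- factor(x, levels = schema[[nm]])
  }
  data
}

# Dummy-coded design matrix (no intercept column) over the given covariates.
covariate_design <- function(data, schema = covariate_schema(),
                             covariates = names(schema)) {
  data <- as_covariate_factors(data, schema, covariates)
  if (nrow(data) == 0L) {
    terms <- schema_terms(schema[covariates])
    return(matrix(numeric(0), nrow = 0L, ncol = length(terms),
      dimnames = list(NULL, terms)
    ))
  }
  X <- model.matrix(reformulate(covariates), data[, covariates, drop = FALSE])
  X[, setdiff(colnames(X), "(Intercept)"), drop = FALSE]
}

#' Default covariate category margins
#'
#' Marginal category probabilities for the synthetic cohort, proportional to
#' the descriptive counts of a register cohort of roughly 67,000 long-term
#' sick-listed persons observed during an economic-growth period (about 60%
#' women, dominant wage-earner and office-work categories, 37% with prior
#' sickness absence, 24% with prior unemployment).
#'
#' @return Named list: covariate name -> named numeric vector of category
#'   probabilities (summing to 1).
#' @export
default_covariate_margins <- function() {
  norm <- function(x) x / sum(x)
  list(
    gender = norm(c(female = 39988, male = 26848)),
    age_group = norm(c(`50-59` = 25108, `20-29` = 7279, `30-39` = 14805, `40-49` = 19644)),
    socio_economic = norm(c(
      wage_earner = 61810, self_employed = 833,
      without_job = 4191, unregistered = 2
    )),
    job_type = norm(c(
      sale_service_care = 12086, military = 2038, management = 1103,
      office = 23298, farming_transport = 11847, other = 15137,
      unregistered = 1327
    )),
    chronic_disease = norm(c(no = 65058, yes = 1778)),
    prior_sa = norm(c(none = 42007, one_plus = 24829)),
    prior_unemp = norm(c(none = 50597, one = 5440, two_plus = 10799))
  )
}
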