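---
title: "Predicting one-year labour-market outcomes for long-term sick-listed persons"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting one-year labour-market outcomes for long-term sick-listed persons}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

A person who has been sick-listed for four weeks or more may, one year
later, be back at work, unemployed, sick again, still in the same sickness
episode, on a disability pension, or temporarily outside the labour market
(maternity leave, education benefits). Caseworkers who allocate
return-to-work resources would like a personal risk profile over these six
outcomes at the moment the long-term episode begins, using only information
available on that day.

`sickpaths` implements two predictors of the day-365 state and the
machinery to compare them on register-like data:

* **A multi-state hazard predictor.** Daily movement between the six states
  — `LTS` (the initial long-term sickness episode), `W` (work), `U`
  (unemployment), `SA` (recurrent sickness absence), `D` (disability
  pension, absorbing) and `TO` (temporary out) — is described by 20
  transition-specific Cox proportional hazards models on a common clock
  (days since the initial sick-listing, with left truncation at sojourn
  entry). Because no tractable closed form combines 20 fitted transitions
  into a one-year state-occupation probability, the package follows the
  discrete-event-simulation route: simulate many daily pathways per person
  from the fitted hazards and read off the fraction ending in each state.
* **A logistic comparator.** One additive binary logistic regression per
  outcome state, the field's standard approach.

Both are scored on a held-out validation set with per-person Brier scores
against the covariate-free null model, and with tie-corrected ROC/AUC.

Because the registers such analyses run on are not distributable, the
package ships a first-class synthetic-data module: a generator that draws
register-like benefit spells from a *known* ground-truth hazard model, so
that every downstream stage — timeline derivation, risk sets, Cox fits, the
simulation, the scoring — can be verified against either exact oracles or
the generating truth.

## Data model

The raw unit is a **spell**: one dated benefit interval per person
(`SICK`, `UNEMP`, `DISAB`, `TEMPOUT`), half-open `[start_day, end_day)` on
a 0-based integer day grid. Work is the *absence* of spells, following the
register convention that benefit-free days mean self-support. Calendar
dates are out of scope; the day grid makes tiling and length arithmetic
unambiguous.

`derive_timeline()` turns spells into **maximal state runs**: sickness
becomes `SA`, gaps become `W`, every day at or after the first disability
spell is `D` (absorbing — later spells are ignored), and observation is
clipped at the censoring day (the combined age-60 / emigration / death
truncation). `find_initial_lts()` locates the first sickness episode of at
least 28 days (4 weeks) whose start lies in the inclusion window; the first
year of each scenario is a buffer from which no one is indexed, so a full
365-day look-back exists for everyone. `mark_initial_lts()` relabels the
episode `LTS` from the index day until the first transition; recurrent
sickness afterwards is `SA`, never `LTS` again (the state graph has no
edges back into `LTS`).

Seven baseline covariates form the prediction basis: gender, age group
(20–29/30–39/40–49/50–59), socio-economic position, job type (7
categories), chronic-disease insurance, and two look-back variables —
prior sickness-absence episodes (`none`/`one_plus`) and prior unemployment
episodes (`none`/`one`/`two_plus`) counted as maximal runs intersecting the
365 days before the index day. Covariates are fixed at baseline in both
fitting and prediction: pathways are unknown in advance, so a predictor
cannot use time-varying information, and the fitted hazards must condition
on the same information set the predictions will have.

## The synthetic generator

`simulate_histories()` is the package's study-condition definition, not a
tuning knob:

* Covariates are drawn independently from margins proportional to a
  register cohort of long-term sick-listed persons in a growth economy
  (about 60% women, 92% wage earners, 37% with prior sickness absence).
  Correlation between covariates is deliberately not modelled; nothing in
  the available descriptives constrains it.
* Look-back episodes are *planted* to match the sampled prior-SA /
  prior-unemployment categories (one episode for `one_plus`, two for
  `two_plus`), with at least one work day between episodes and before the
  index so that maximal-run counting recovers the categories exactly.
  Planted sickness spells are at least 14 days long, reflecting that only
  absence beyond 13 consecutive days reaches the register.
* From the index day the trajectory steps forward one day at a time under
  competing exponential hazards: with per-transition daily rates `d_k`, the
  stay probability is `exp(-sum(d))` and exits are allocated
  proportionally, `(d_k / sum(d)) * (1 - exp(-sum(d)))` — one joint
  categorical draw per day. Independent per-edge Bernoulli draws were
  rejected because they can produce two transitions in one day; the joint
  draw is a valid probability vector for any hazard magnitudes.
* Exits from `LTS` are suppressed for the first 27 days so the shortest
  initial episode is exactly 28 days (a draw during day *t* lands at
  *t*+1). Forward sickness sojourns after `LTS` take whatever length the
  hazards produce, with no 14-day floor: imposing one would make the
  process non-Markov on the day grid and break the exactness of the
  matrix-product oracle below. Only the *planted look-back* spells carry
  the registration minimum.
* A constant daily censoring hazard (default `5e-5`, about 1.8% of persons
  per year) collapses age-60, emigration and death into one independent
  right-truncation process. No published rate constrains this; it was fixed
  once at a realistically small value.

The default generating models (`true_model_growth()`,
`true_model_recession()`, `true_model_null()`) were chosen once to echo the
qualitative features of the observed registry: roughly 4% of persons still
in `LTS` after one year, a transition mix dominated by work, sickness and
unemployment moves with rare disability entries, and covariate effects
planted where the literature finds them — male gender, middle age and
self-employment favouring return to work; joblessness, chronic disease,
prior sickness and above all prior unemployment working against it; chronic
disease and older age raising disability risk. The recession variant
lowers work-return rates, raises unemployment flows and steepens the
prior-unemployment gradient. Calibrating the generator to reproduce any
published transition table exactly is a non-goal; the generator's job is to
make planted structure recoverable, not to impersonate a specific registry.

## Transition models

`build_risk_sets()` produces one record per maximal sojourn in a
transition's from-state intersecting `(0, 365]` days since the index:
entry (left truncation), exit, and an event indicator that is 1 only when
the sojourn ends in the target state — competing exits are censoring for
each cause-specific model. `fit_transition_cox()` maximises the Cox partial
likelihood with **Breslow** tie handling (ties are massive on an integer
day grid) and retains the Breslow baseline cumulative hazard at the
reference covariate pattern. The daily increment used downstream for day
*t* is the jump of the cumulative hazard over `(t, t+1]`, zero beyond the
last observed event day.

Numerical policy for degenerate designs, decided once:

* dummy columns without variation in a risk set are dropped and recorded;
* terms whose estimate comes back non-finite (singular or fully separated
  sparse cells) are dropped and the model refitted;
* a monotone partial likelihood on a rare edge (a handful of events spread
  over many covariate levels) is recorded as a flag rather than surfaced as
  an optimiser warning — the huge standard errors already tell the story;
* edges with zero observed events are excluded from the fitted set with a
  warning, and the simulation treats their hazard as zero. Rare edges with
  at least one event are kept.

## The discrete event simulation and its oracle

For a person with covariate vector *x*, `predict_state_occupation()`
repeats: start in `LTS` at day 0; each day, convert the fitted per-edge
increments `dLambda_0k(t) exp(x'b_k)` into the one-day probability vector
above; draw the next state; stop at day 365. The default 10,000 pathways
per person give a Monte-Carlo standard error of at most
`0.5 / sqrt(10000) = 0.005` per state; `n_reps` scales down for quick
runs. Persons sharing a covariate pattern share one batch of pathways —
the prediction depends on covariates only — and all randomness flows
through one seed with a fixed unit ordering, so results are exactly
reproducible. (Counter-based per-person substreams were considered; base R
has no counter-based generator, so reproducibility is provided by the
deterministic ordering instead.)

`markov_oracle()` computes the same quantity *exactly*: the day-grid
process is Markov, so the occupation distribution at day 365 is the unit
vector on `LTS` multiplied by the ordered product of the 365 one-step
6-by-6 matrices. The simulation is verified against the oracle (within
3 Monte-Carlo standard errors per state) across fixed and randomized
hazard settings; the generator itself is verified against the oracle run
on the *true* model. For tests the `lts_hold_days` argument reproduces the
generator's initial-episode hold; fitted models need no hold because the
data already contain no early `LTS` exits.

## Evaluation

* **Brier score**: `(y - p)^2` per person; the null model predicts the
  training prevalence for everyone, giving `q(1-p)^2 + (1-q)p^2` on a
  validation set with prevalence `q` (for example, a constant prediction of
  0.662 against prevalence 0.662 scores 0.22 after rounding).
* **AUC** by the rank statistic with ties counted 1/2, so a constant
  predictor scores exactly 0.5. Discrimination bands follow the
  conventional guide (0.9–1.0 excellent down to below 0.6 fail), with
  intervals closed on the left — an AUC of exactly 0.8 is "good". The
  guide itself is ambiguous at boundaries; left-closure was fixed once.
* **Variable importance**: refit the logistic model without one variable;
  `delta_AUC% = 100 (AUC_full - AUC_reduced) / AUC_full`, and the Brier
  analogue with the sign arranged so positive means accuracy lost on
  removal. The relative-change form was chosen because it produces the
  small percentage magnitudes such tables conventionally report.
* Censored-before-365 persons are excluded from logistic fitting and from
  every metric; DES predictions are still produced for them but never
  scored. How censored persons should enter a one-year outcome is
  underdetermined, and exclusion is the conservative reading. The six
  logistic probabilities of a person are six separate binary models and do
  **not** sum to 1; that is a property of the comparator's design and is
  asserted nowhere.
* A validation state with no cases (possible for disability in small
  synthetic runs) gets `NA` AUC with a warning rather than a crash.

## The pipeline

`run_experiment()` wires everything together per scenario: generate,
derive, assemble the cohort, split train/validation at a 67.4% training
share (the two-thirds convention), count transitions, fit 20 Cox and 6
logistic models on training, predict for validation with both methods, and
score. Scenarios are independent synthetic cohorts with their own
generating models — reusing one sample across macroeconomic periods would
age the sample and deplete it of disability exits, a bias not worth
importing into a testbed. All randomness derives from one root seed split
into named substreams (generation, split, DES), and rerunning a
configuration reproduces byte-identical artifacts.

```{r example, eval = FALSE}
library(sickpaths)

cfg <- experiment_config(
  scenarios = list(growth = true_model_growth()),
  n_persons = 6000, n_reps = 400, seed = 1
)
res <- run_experiment(cfg)
res$report     # Table of prevalence / AUC / Brier per state and method
res$importance # leave-one-variable-out importance for the work state
autoplot(res)  # AUC dot plot per state and method
```

## Problem sizes and what the tests show

The shipped tests and the acceptance script run deliberately scaled-down
study conditions, chosen as the package's own verification sizes: toy
constant-hazard models with 1,500–10,000 pathways for simulation-vs-oracle
agreement; 2,500–5,000 persons for generator-vs-oracle and discrete-time
Aalen–Johansen agreement; 4,000–6,000 persons with 200–400 pathways for
end-to-end ordering checks (informative predictors beat the null model on
work; a null generating model yields chance-level AUC everywhere); and
20,000 persons for parameter recovery, where at least 95% of the fitted
log hazard ratios across all fitted edges must lie within 3 standard
errors of the generating values.

Passing these tests shows that the machinery is correct on data whose
generating process is known and matches the model class. It does not show
that real register data satisfy proportional hazards, independent
censoring, or covariate-independent spell registration — and the generator
deliberately omits covariate correlation, seasonal and calendar effects,
policy changes within periods, and the unrecorded transitions (e.g. a
sick-listed employee being laid off mid-episode) that bias real registers.

## Known limitations

* Baseline-covariate-only hazards: sojourn-entry updating of covariates is
  structurally possible in the risk-set code but deliberately not exposed,
  because predictions cannot condition on information unavailable at
  baseline.
* No interactions, stratified models, penalisation or categorised
  continuous covariates in either predictor.
* Per-person DES cost grows with the number of distinct covariate
  patterns; the pattern-sharing shortcut removes the duplicate work but a
  cohort of fully distinct patterns pays full price.
* Confidence intervals for AUC and Brier differences are not provided.
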