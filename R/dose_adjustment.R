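# Exposure-matched dose adjustment: find the renal-impairment dose whose
# population AUC_0-t matches healthy exposure, plus box-whisker summaries.

#' Population AUC_0-t distribution
#'
#' Simulates the ensemble, runs per-subject NCA, and returns the per-subject
#' AUC_0-t samples (t = the scenario horizon).
#'
#' @param drug A `drug_parameters` object.
#' @param population A population tibble.
#' @param scenario A [dose_scenario()].
#' @param rtol,atol Solver tolerances.
#' @return A tibble `subject_id`, `auc` (ug*h/mL).
#' @export
auc_distribution <- function(drug, population, scenario,
                             rtol = 1e-6, atol = 1e-8) {
  profiles <- simulate_population(drug, population, scenario,
                                  rtol = rtol, atol = atol)
  nca_population(profiles, dose_mg = scenario$dose_mg,
                 route = scenario$route) |>
    dplyr::transmute(subject_id = .data$subject_id, auc = .data$AUC_0_t)
}

#' Box-whisker summary of AUC samples
#'
#' @param auc Numeric vector (or a tibble with an `auc` column).
#' @return A one-row tibble `p5`, `q1`, `median`, `q3`, `p95` (ordered).
#' @export
box_summary <- function(auc) {
  if (is.data.frame(auc)) auc <- auc$auc
  q <- quantile(auc, c(0.05, 0.25, 0.5, 0.75, 0.95), names = FALSE)
  tibble::tibble(p5 = q[1], q1 = q[2], median = q[3], q3 = q[4], p95 = q[5])
}

#' Match a renal-impairment dose to a target exposure
#'
#' Searches the dose whose population summary AUC_0-t equals `target_auc`
#' within `tol`. The search starts from the linear-kinetics guess
#' `dose * target / achieved` and falls back to bisection on the dose bounds;
#' under linear PK the guess converges in at most two evaluations.
#'
#' @param drug A `drug_parameters` object.
#' @param population The renally impaired population tibble.
#' @param scenario The reference [dose_scenario()] (its `dose_mg` is the
#'   reference dose).
#' @param target_auc Target exposure in ug*h/mL (> 0).
#' @param tol Relative tolerance on the matched AUC (default 2%).
#' @param dose_bounds Dose bracket in mg.
#' @param statistic Population summary statistic (default `median`).
#' @param auc_fn Optional override: a function `dose -> summary AUC`,
#'   replacing the simulator (used for analytic surrogates and testing).
#' @return A one-row tibble: `stage`, `reference_dose`, `adjusted_dose`,
#'   `practical_dose` (nearest 25 mg), `reduction_pct`, `target_auc`,
#'   `achieved_auc`, `n_evaluations`.
#' @export
match_dose <- function(drug, population, scenario, target_auc, tol = 0.02,
                       dose_bounds = c(12.5, 1600), statistic = median,
                       auc_fn = NULL) {
  if (target_auc <= 0) abort("match_dose: target_auc must be > 0")
  stage <- if (!is.null(population) && "stage" %in% names(population)) {
    population$stage[1]
  } else {
    NA_character_
  }
  if (is.null(auc_fn)) {
    auc_fn <- function(dose) {
      sc <- scenario
      sc$dose_mg <- dose
      statistic(auc_distribution(drug, population, sc)$auc)
    }
  }
  n_eval <- 0L
  eval_auc <- function(dose) {
    n_eval <<- n_eval + 1L
    auc_fn(dose)
  }

  ref_dose <- scenario$dose_mg
  dose <- ref_dose
  achieved <- eval_auc(dose)
  for (i in 1:3) {
    if (abs(achieved - target_auc) <= tol * target_auc) break
    dose <- dose * target_auc / achieved  # linear-PK proportional update
    if (dose < dose_bounds[1] || dose > dose_bounds[2]) {
      abort("match_dose: solution outside dose_bounds; widen the bracket")
    }
    achieved <- eval_auc(dose)
  }
  if (abs(achieved - target_auc) > tol * target_auc) {
    # bisection fallback for any residual non-linearity
    lo <- dose_bounds[1]; hi <- dose_bounds[2]
    f_lo <- eval_auc(lo) - target_auc
    f_hi <- eval_auc(hi) - target_auc
    if (sign(f_lo) == sign(f_hi)) {
      abort("match_dose: target not bracketed by dose_bounds; widen the bracket")
    }
    for (i in 1:40) {
      dose <- (lo + hi) / 2
      achieved <- eval_auc(dose)
      if (abs(achieved - target_auc) <= tol * target_auc) break
      if (sign(achieved - target_auc) == sign(f_lo)) lo <- dose else hi <- dose
    }
  }
  tibble::tibble(
    stage = stage, reference_dose = ref_dose, adjusted_dose = dose,
    practical_dose = 25 * round(dose / 25),
    reduction_pct = 100 * (1 - dose / ref_dose),
    target_auc = target_auc, achieved_auc = achieved, n_evaluations = n_eval
  )
}

#' Stagewise dose recommendations matching healthy exposure
#'
#' Samples a healthy and three renally impaired populations (the stage demo-
#' graphics default to the impaired cohort means), takes the healthy summary
#' AUC_0-t at the reference dose as the target, and matches the dose per
#' stage.
#'
#' @param drug A `drug_parameters` object.
#' @param reference_dose Reference oral dose in mg.
#' @param n Individuals per population.
#' @param seed Integer seed.
#' @param horizon_h Shared AUC window (identical for healthy and impaired).
#' @param grid_dt Output grid spacing in h (0.2 h keeps the AUC ratio stable
#'   while holding population runs fast).
#' @param statistic Population summary statistic (default `median`).
#' @param tol Relative matching tolerance.
#' @return A tibble with one [match_dose()] row per impaired stage, plus the
#'   healthy target in `target_auc`.
#' @export
ri_dose_recommendations <- function(drug, reference_dose = 200, n = 40, seed,
                                    horizon_h = 72, grid_dt = 0.2,
                                    statistic = median, tol = 0.02) {
  if (missing(seed)) abort("ri_dose_recommendations: a seed is mandatory")
  scenario <- dose_scenario("oral", reference_dose, horizon_h = horizon_h,
                            grid_dt = grid_dt)
  demo <- list(
    healthy = list(weight = 71, age = 28),
    mild = list(weight = 63.6, age = 58),
    moderate = list(weight = 72.4, age = 63),
    severe = list(weight = 74.4, age = 64)
  )
  pop_for <- function(stage, seed_offset) {
    sample_population(population_spec(
      n = n, stage = stage,
      age_mean = demo[[stage]]$age, weight_mean = demo[[stage]]$weight,
      seed = seed + seed_offset
    ))
  }
  healthy_auc <- auc_distribution(drug, pop_for("healthy", 0L), scenario)
  target <- statistic(healthy_auc$auc)
  purrr::imap_dfr(c(mild = 1L, moderate = 2L, severe = 3L), function(off, stage) {
    match_dose(drug, pop_for(stage, off), scenario, target_auc = target,
               statistic = statistic, tol = tol)
  })
}
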