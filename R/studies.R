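# Packaged study designs: the demographics/dosing of the literature cohorts
# behind the PRE/OBS tables, with the simulation settings used to reproduce
# their NCA parameters (infusion durations and the multiple-dose regimen are
# not reported and are fixed package choices; horizons are 24 h for healthy
# single-dose studies, 72 h for renal impairment, 96 h for the q12h
# multiple-dose study).

#' Study design table
#'
#' One row per evaluated study profile: demographics (cohort means), route,
#' dose, and the simulation settings (number of doses, interval, infusion
#' duration, horizon).
#'
#' @return A tibble keyed by `study`.
#' @export
study_designs <- function() {
  demo <- read_packaged_csv("table1_demographics.csv")
  multi <- c("flor_iv", "flor_po")
  demo |>
    dplyr::mutate(
      n_doses = dplyr::if_else(.data$study %in% multi, 8L, 1L),
      interval_h = 12,
      infusion_h = dplyr::if_else(.data$dose_mg >= 400, 1, 0.5),
      horizon_h = dplyr::case_when(
        .data$study %in% multi ~ 96,
        .data$cohort != "healthy" ~ 72,
        TRUE ~ 24
      ),
      sex = dplyr::if_else(!is.na(.data$female_pct) & .data$female_pct > 50,
                           "F", "M")
    )
}

study_individual <- function(design_row) {
  ind <- make_reference_individual(
    age = design_row$age_y, weight = design_row$weight_kg,
    height = if (design_row$sex == "F") 163 else 176, sex = design_row$sex
  )
  if (design_row$cohort != "healthy") {
    ind <- apply_renal_impairment(ind, design_row$cohort)
  }
  ind
}

study_scenario <- function(design_row, grid_dt = 0.05) {
  dose_scenario(
    route = design_row$route, dose_mg = design_row$dose_mg,
    infusion_h = design_row$infusion_h, n_doses = design_row$n_doses,
    interval_h = design_row$interval_h, horizon_h = design_row$horizon_h,
    grid_dt = grid_dt
  )
}

#' Predicted NCA parameters for every packaged study
#'
#' Simulates each study's mean-demographic individual under its design and
#' extracts Cmax, AUC_0-t (t = the study horizon) and apparent CL by NCA.
#' For the multiple-dose study the tabulated convention is followed: AUC_0-t
#' accumulates over the full sampling horizon and CL is the single
#' administration dose divided by AUC.
#'
#' @param drug A `drug_parameters` object (default [ofloxacin()]).
#' @param studies Optional character vector restricting the study set.
#' @param grid_dt Output grid spacing in h.
#' @return A tibble: `study`, `cohort`, `route`, `dose_mg`, `Cmax`,
#'   `AUC_0_t`, `CL`.
#' @export
predict_study_nca <- function(drug = ofloxacin(), studies = NULL,
                              grid_dt = 0.05) {
  designs <- study_designs()
  if (!is.null(studies)) {
    designs <- designs[designs$study %in% studies, ]
  }
  purrr::map_dfr(seq_len(nrow(designs)), function(i) {
    row <- designs[i, ]
    prof <- simulate_profile(build_model(drug, study_individual(row)),
                             study_scenario(row, grid_dt = grid_dt))
    res <- run_nca(prof, dose_mg = row$dose_mg, route = row$route)
    tibble::tibble(study = row$study, cohort = row$cohort, route = row$route,
                   dose_mg = row$dose_mg, Cmax = res$Cmax,
                   AUC_0_t = res$AUC_0_t, CL = res$CL)
  })
}

#' Compare simulator predictions with the packaged observed values
#'
#' Joins [predict_study_nca()] against the packaged observed NCA parameters
#' and flags each fold error against the 0.5-2 acceptance band.
#'
#' @param drug A `drug_parameters` object (default [ofloxacin()]).
#' @param grid_dt Output grid spacing in h.
#' @return A tidy tibble: `study`, `cohort`, `parameter`, `predicted`
#'   (simulated here), `observed` (packaged), `fold_error`, `within`.
#' @export
simulated_vs_observed <- function(drug = ofloxacin(), grid_dt = 0.05) {
  pred <- predict_study_nca(drug, grid_dt = grid_dt) |>
    tidyr::pivot_longer(cols = c("Cmax", "AUC_0_t", "CL"),
                        names_to = "parameter", values_to = "predicted")
  obs <- load_pk_pairs("all") |>
    dplyr::select("study", "parameter", observed = "observed")
  pred |>
    dplyr::inner_join(obs, by = c("study", "parameter")) |>
    fold_error_within()
}
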