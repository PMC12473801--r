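# Shared builders for fast test runs.

ofx <- ofloxacin()

ref_individual <- function(...) make_reference_individual(...)

healthy_cohort_individual <- function() {
  make_reference_individual(age = 28, weight = 71, height = 175, sex = "M")
}

fast_iv <- function(dose = 200, horizon = 24) {
  dose_scenario("iv_infusion", dose, infusion_h = 0.5, horizon_h = horizon,
                grid_dt = 0.1)
}

fast_po <- function(dose = 200, horizon = 24) {
  dose_scenario("oral", dose, horizon_h = horizon, grid_dt = 0.1)
}

# mono-exponential synthetic profile for NCA oracle checks
monoexp_profile <- function(C0, k, times) {
  tibble::tibble(time_h = times, conc_ug_ml = C0 * exp(-k * times))
}

# drug record variants without re-reading YAML
drug_with <- function(drug, ...) {
  mods <- list(...)
  for (nm in names(mods)) drug[[nm]] <- mods[[nm]]
  drug
}
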