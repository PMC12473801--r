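# Virtual physiologies: a healthy reference adult, chronic kidney disease
# (CKD) stage scaling, and seeded population sampling.

REF_AGE <- 30
REF_WEIGHT <- 73
REF_HEIGHT <- 176

# hard demographic validity bounds shared by the builder and the sampler
DEMO_BOUNDS <- list(age = c(18, 80), weight = c(30, 150), height = c(120, 210))

#' Reference organ volumes and regional blood flows
#'
#' Packaged ICRP-style adult reference table (male, 30 y, 73 kg, 176 cm).
#' Cardiac output equals the sum of the regional arterial flows; lung receives
#' the whole cardiac output in series and carries no regional flow entry.
#'
#' @return A tibble with columns `organ`, `volume_l`, `flow_l_per_h`.
#' @export
reference_physiology <- function() {
  read_packaged_csv("reference_physiology.csv")
}

#' Body surface area (DuBois)
#'
#' @param weight Body weight in kg.
#' @param height Height in cm.
#' @return Body surface area in m^2.
#' @export
bsa_dubois <- function(weight, height) {
  0.007184 * weight^0.425 * height^0.725
}

#' Renal function stage table
#'
#' CKD severity grades with their mean estimated glomerular filtration rate
#' (eGFR, mL/min/1.73 m^2), the eGFR sampling range used in population mode,
#' and the stage-specific physiological modifiers: hematocrit, the plasma
#' binding-protein concentration ratio relative to healthy (`protein_scaling`,
#' < 1 in CKD reflecting hypoalbuminemia), gastric emptying time, small
#' intestinal transit time, and the acidic-phospholipid association constant
#' `ka_ap` used by the tissue partitioning model (raised from 0.55 to 1.3 in
#' renal impairment).
#'
#' @return A tibble with one row per stage (healthy, mild, moderate, severe).
#' @export
renal_stages <- function() {
  tibble::tribble(
    ~stage,     ~egfr_mean, ~egfr_lo, ~egfr_hi, ~hematocrit, ~protein_scaling,
    ~gastric_emptying_h, ~si_transit_h, ~ka_ap,
    "healthy",  110,        90,       130,      NA,          1.00, 0.50, 3.8, 0.55,
    "mild",     40,         30,       50,       0.42,        0.96, 0.65, 4.2, 1.30,
    "moderate", 25,         15,       30,       0.38,        0.92, 0.80, 4.6, 1.30,
    "severe",   8,          5,        14,       0.33,        0.86, 1.00, 5.0, 1.30
  )
}

stage_row <- function(stage) {
  stages <- renal_stages()
  if (!stage %in% stages$stage) {
    abort(paste0("unknown renal stage: '", stage,
                 "' (expected healthy, mild, moderate or severe)"))
  }
  stages[stages$stage == stage, ]
}

check_demographic <- function(value, field) {
  b <- DEMO_BOUNDS[[field]]
  if (!is.numeric(value) || length(value) != 1 || is.na(value) ||
      value < b[1] || value > b[2]) {
    abort(paste0("invalid ", field, ": must be a number in [", b[1], ", ",
                 b[2], "], got ", paste(value, collapse = ", ")))
  }
  invisible(value)
}

#' Build a healthy reference individual
#'
#' Constructs a complete virtual physiology by allometric scaling of the
#' packaged reference table: organ volumes scale linearly with body weight,
#' regional blood flows (and hence cardiac output) with body surface area.
#' Absolute GFR is derived from the surface-normalized eGFR as
#' `GFR_abs = eGFR * (BSA / 1.73) * 0.06` L/h.
#'
#' @param age Age in years (18-80).
#' @param weight Body weight in kg (30-150).
#' @param height Height in cm (120-210).
#' @param sex `"M"` or `"F"` (sets hematocrit 0.45 / 0.40).
#' @param egfr Estimated GFR in mL/min/1.73 m^2 (healthy default 110).
#' @return A one-row tibble: demographics, hematocrit, BSA, cardiac output,
#'   eGFR and absolute GFR, CKD-relevant scaling factors (protein scaling,
#'   gastric emptying, intestinal transit, `ka_ap`), the stage label, and a
#'   nested `organs` tibble (`organ`, `volume_l`, `flow_l_per_h`).
#' @export
make_reference_individual <- function(age = REF_AGE, weight = REF_WEIGHT,
                                      height = REF_HEIGHT, sex = c("M", "F"),
                                      egfr = 110) {
  sex <- match.arg(sex)
  check_demographic(age, "age")
  check_demographic(weight, "weight")
  check_demographic(height, "height")
  if (egfr <= 0) abort("invalid egfr: must be > 0")

  ref <- reference_physiology()
  bsa <- bsa_dubois(weight, height)
  bsa_ref <- bsa_dubois(REF_WEIGHT, REF_HEIGHT)

  organs <- ref |>
    dplyr::mutate(
      volume_l = .data$volume_l * weight / REF_WEIGHT,
      flow_l_per_h = .data$flow_l_per_h * bsa / bsa_ref
    )
  healthy <- stage_row("healthy")

  tibble::tibble(
    subject_id = 1L,
    age = age, weight = weight, height = height, sex = sex,
    hematocrit = if (sex == "M") 0.45 else 0.40,
    bsa_m2 = bsa,
    cardiac_output_l_h = sum(organs$flow_l_per_h, na.rm = TRUE),
    egfr = egfr,
    gfr_abs_l_h = egfr * (bsa / 1.73) * 0.06,
    protein_scaling = healthy$protein_scaling,
    gastric_emptying_h = healthy$gastric_emptying_h,
    si_transit_h = healthy$si_transit_h,
    ka_ap = healthy$ka_ap,
    stage = "healthy",
    organs = list(organs)
  )
}

#' Apply a renal-impairment stage to a healthy individual
#'
#' Sets the eGFR to the stage mean (or a supplied draw), recomputes absolute
#' GFR, raises the acidic-phospholipid association constant `ka_ap` to 1.3 for
#' any impaired stage, and applies the stage defaults for hematocrit, plasma
#' binding-protein scaling, gastric emptying and intestinal transit. All other
#' fields are preserved.
#'
#' @param individual A one-row individual tibble (healthy-configured).
#' @param stage `"healthy"`, `"mild"`, `"moderate"` or `"severe"`.
#' @param egfr Optional eGFR draw overriding the stage mean (population mode).
#' @param modifiers Optional named list overriding the stage defaults for any
#'   of `hematocrit`, `protein_scaling`, `gastric_emptying_h`, `si_transit_h`,
#'   `ka_ap`. Overrides on the healthy stage that contradict the healthy
#'   defaults raise a warning (not an error).
#' @return The modified one-row individual tibble.
#' @export
apply_renal_impairment <- function(individual, stage, egfr = NULL,
                                   modifiers = list()) {
  srow <- stage_row(stage)
  out <- individual

  if (stage == "healthy") {
    if (length(modifiers)) {
      warn("overrides on the healthy stage contradict healthy defaults; applying them anyway")
      for (nm in names(modifiers)) out[[nm]] <- modifiers[[nm]]
    }
    if (!is.null(egfr)) {
      out$egfr <- egfr
      out$gfr_abs_l_h <- egfr * (out$bsa_m2 / 1.73) * 0.06
    }
    return(out)
  }

  out$egfr <- egfr %||% srow$egfr_mean
  out$gfr_abs_l_h <- out$egfr * (out$bsa_m2 / 1.73) * 0.06
  defaults <- list(
    hematocrit = srow$hematocrit,
    protein_scaling = srow$protein_scaling,
    gastric_emptying_h = srow$gastric_emptying_h,
    si_transit_h = srow$si_transit_h,
    ka_ap = srow$ka_ap
  )
  for (nm in names(defaults)) {
    out[[nm]] <- modifiers[[nm]] %||% defaults[[nm]]
  }
  out$stage <- stage
  out
}

#' Specify a virtual population
#'
#' Demographics are sampled from truncated normal distributions
#' (`mean`, coefficient of variation, truncated at mean +/- 3.5 SD and at the
#' validity bounds); organ volumes and flows receive individual mean-one
#' log-normal multipliers; eGFR is sampled uniformly within the stage range
#' (override with `egfr_range`; a degenerate range pins it).
#'
#' @param n Number of individuals (>= 1).
#' @param stage Renal stage label.
#' @param age_mean,age_cv,weight_mean,weight_cv,height_mean,height_cv
#'   Demographic means and coefficients of variation.
#' @param female_fraction Fraction of females in `[0, 1]`.
#' @param cv_volumes,cv_flows Log-normal coefficients of variation applied per
#'   organ volume / regional flow.
#' @param egfr_range Length-2 numeric overriding the stage eGFR sampling
#'   range; `NULL` uses the stage table. If every variability source is zero
#'   the stage-mean eGFR is used, so a fully degenerate spec reproduces the
#'   reference individual.
#' @param seed Integer seed (mandatory; population sampling is seeded).
#' @return A `population_spec` list for [sample_population()].
#' @export
population_spec <- function(n, stage = "healthy",
                            age_mean = REF_AGE, age_cv = 0.15,
                            weight_mean = REF_WEIGHT, weight_cv = 0.15,
                            height_mean = REF_HEIGHT, height_cv = 0.05,
                            female_fraction = 0.5,
                            cv_volumes = 0.1, cv_flows = 0.1,
                            egfr_range = NULL, seed) {
  if (missing(seed)) abort("population_spec: a seed is mandatory")
  if (n < 1) abort("population_spec: n must be >= 1")
  cvs <- c(age_cv, weight_cv, height_cv, cv_volumes, cv_flows)
  if (any(cvs < 0)) abort("population_spec: coefficients of variation must be >= 0")
  if (female_fraction < 0 || female_fraction > 1) {
    abort("population_spec: female_fraction must be in [0, 1]")
  }
  srow <- stage_row(stage)
  egfr_range <- egfr_range %||% c(srow$egfr_lo, srow$egfr_hi)
  if (length(egfr_range) != 2 || diff(egfr_range) < 0 || egfr_range[1] <= 0) {
    abort("population_spec: egfr_range must be an ascending positive pair")
  }
  structure(
    list(n = as.integer(n), stage = stage,
         age_mean = age_mean, age_cv = age_cv,
         weight_mean = weight_mean, weight_cv = weight_cv,
         height_mean = height_mean, height_cv = height_cv,
         female_fraction = female_fraction,
         cv_volumes = cv_volumes, cv_flows = cv_flows,
         egfr_range = egfr_range, seed = as.integer(seed)),
    class = "population_spec"
  )
}

rtruncnorm1 <- function(mean, cv, bounds) {
  if (cv == 0) return(mean)
  sdv <- mean * cv
  lo <- max(bounds[1], mean - 3.5 * sdv)
  hi <- min(bounds[2], mean + 3.5 * sdv)
  if (lo >= hi) abort("empty demographic sampling range after truncation")
  repeat {
    x <- rnorm(1, mean, sdv)
    if (x >= lo && x <= hi) return(x)
  }
}

lognormal_multiplier <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  exp(rnorm(n, -sdlog^2 / 2, sdlog))
}

#' Sample a virtual population
#'
#' Deterministic under the spec's seed: the same spec yields an identical
#' population tibble.
#'
#' @param spec A [population_spec()].
#' @return A tibble of `spec$n` individual rows (same columns as
#'   [make_reference_individual()]).
#' @export
sample_population <- function(spec) {
  stopifnot(inherits(spec, "population_spec"))
  withr::with_seed(spec$seed, {
    rows <- purrr::map(seq_len(spec$n), function(i) {
      sex <- if (runif(1) < spec$female_fraction) "F" else "M"
      ind <- make_reference_individual(
        age = rtruncnorm1(spec$age_mean, spec$age_cv, DEMO_BOUNDS$age),
        weight = rtruncnorm1(spec$weight_mean, spec$weight_cv, DEMO_BOUNDS$weight),
        height = rtruncnorm1(spec$height_mean, spec$height_cv, DEMO_BOUNDS$height),
        sex = sex
      )
      organs <- ind$organs[[1]]
      organs$volume_l <- organs$volume_l *
        lognormal_multiplier(nrow(organs), spec$cv_volumes)
      organs$flow_l_per_h <- organs$flow_l_per_h *
        lognormal_multiplier(nrow(organs), spec$cv_flows)
      ind$organs[[1]] <- organs
      ind$cardiac_output_l_h <- sum(organs$flow_l_per_h, na.rm = TRUE)

      egfr <- if (diff(spec$egfr_range) == 0) spec$egfr_range[1] else
        runif(1, spec$egfr_range[1], spec$egfr_range[2])
      ind <- apply_renal_impairment(ind, spec$stage, egfr = egfr)
      ind$subject_id <- i
      ind
    })
    dplyr::bind_rows(rows)
  })
}

#' Flatten a population to one wide row per individual
#'
#' Expands the nested organ table into `vol_*` / `flow_*` columns so a
#' population can be written to and read back from plain CSV.
#'
#' @param population A population tibble.
#' @return A wide tibble, one row per individual, all columns atomic.
#' @export
population_to_wide <- function(population) {
  purrr::map_dfr(seq_len(nrow(population)), function(i) {
    row <- population[i, ]
    org <- row$organs[[1]]
    wide <- dplyr::select(row, -"organs")
    vols <- setNames(as.list(org$volume_l), paste0("vol_", org$organ))
    flows <- org[!is.na(org$flow_l_per_h), ]
    fl <- setNames(as.list(flows$flow_l_per_h), paste0("flow_", flows$organ))
    dplyr::bind_cols(wide, tibble::as_tibble(vols), tibble::as_tibble(fl))
  })
}
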