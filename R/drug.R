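# Drug parameter record, diprotic ionization, and the renal/hepatic
# clearance decomposition CL_R = CL_GF + CL_TS.

HEALTHY_EGFR <- 110  # reference eGFR the tubular-secretion term is anchored to

#' Construct a drug parameter record
#'
#' @param name Drug name.
#' @param molecular_mass_g_mol Molecular mass (g/mol).
#' @param pKa_acid,pKa_base Acidic and basic dissociation constants
#'   (`pKa_acid < pKa_base` for a zwitterion).
#' @param logP Lipophilicity (log units).
#' @param fu Fraction unbound in plasma (0 < fu <= 1).
#' @param binding_partner `"albumin"` or `"AGP"`.
#' @param solubility_mg_ml,solubility_ph Aqueous solubility and its reference pH.
#' @param specific_intestinal_permeability_cm_min Transcellular intestinal
#'   permeability (cm/min) referenced to the effective absorptive area.
#' @param specific_organ_permeability_cm_min Specific organ permeability
#'   (cm/min); informational under the perfusion-limited distribution model
#'   (retained for a permeability-limited variant, not used by the solver).
#' @param hepatic_clearance_l_h_kg Total hepatic plasma clearance per kg.
#' @param gfr_fraction Fraction of GFR available to filtration (dimensionless).
#' @param tubular_secretion_l_h Tubular secretion clearance of the healthy
#'   reference (L/h).
#' @param tubular_secretion_exponent Exponent on the eGFR ratio scaling
#'   secretion in renal impairment (`CL_TS = TS * (eGFR/110)^exponent`).
#' @param partition_method Only `"rodgers_rowland"` is implemented.
#' @param cellular_permeability_method Only `"standard"` is implemented.
#' @param logP_range Optional literature range retained for sensitivity runs.
#' @return A `drug_parameters` object (named list).
#' @export
drug_parameters <- function(name, molecular_mass_g_mol, pKa_acid, pKa_base,
                            logP, fu, binding_partner = c("albumin", "AGP"),
                            solubility_mg_ml, solubility_ph = 7,
                            specific_intestinal_permeability_cm_min,
                            specific_organ_permeability_cm_min = NA_real_,
                            hepatic_clearance_l_h_kg,
                            gfr_fraction, tubular_secretion_l_h,
                            tubular_secretion_exponent = 0.3,
                            partition_method = "rodgers_rowland",
                            cellular_permeability_method = "standard",
                            logP_range = NULL) {
  binding_partner <- match.arg(binding_partner)
  partition_method <- match.arg(partition_method)
  if (fu <= 0 || fu > 1) abort("drug_parameters: fu must be in (0, 1]")
  if (pKa_acid >= pKa_base) abort("drug_parameters: pKa_acid must be < pKa_base")
  if (hepatic_clearance_l_h_kg < 0 || tubular_secretion_l_h < 0 ||
      gfr_fraction < 0) {
    abort("drug_parameters: clearance terms must be >= 0")
  }
  if (specific_intestinal_permeability_cm_min <= 0) {
    abort("drug_parameters: permeabilities must be > 0")
  }
  structure(
    list(name = name, molecular_mass_g_mol = molecular_mass_g_mol,
         pKa_acid = pKa_acid, pKa_base = pKa_base, logP = logP, fu = fu,
         binding_partner = binding_partner,
         solubility_mg_ml = solubility_mg_ml, solubility_ph = solubility_ph,
         specific_intestinal_permeability_cm_min =
           specific_intestinal_permeability_cm_min,
         specific_organ_permeability_cm_min =
           specific_organ_permeability_cm_min,
         hepatic_clearance_l_h_kg = hepatic_clearance_l_h_kg,
         gfr_fraction = gfr_fraction,
         tubular_secretion_l_h = tubular_secretion_l_h,
         tubular_secretion_exponent = tubular_secretion_exponent,
         partition_method = partition_method,
         cellular_permeability_method = cellular_permeability_method,
         logP_range = logP_range),
    class = "drug_parameters"
  )
}

#' Read a drug record from YAML
#'
#' @param path Path to a YAML drug record (see the packaged `ofloxacin.yaml`).
#' @return A `drug_parameters` object.
#' @export
read_drug_parameters <- function(path) {
  rec <- yaml::yaml.load_file(path)
  drug_parameters(
    name = rec$name, molecular_mass_g_mol = rec$molecular_mass_g_mol,
    pKa_acid = rec$pKa_acid, pKa_base = rec$pKa_base,
    logP = rec$logP, fu = rec$fu, binding_partner = rec$binding_partner,
    solubility_mg_ml = rec$solubility_mg_ml, solubility_ph = rec$solubility_ph,
    specific_intestinal_permeability_cm_min =
      rec$specific_intestinal_permeability_cm_min,
    specific_organ_permeability_cm_min =
      rec$specific_organ_permeability_cm_min,
    hepatic_clearance_l_h_kg = rec$hepatic_clearance_l_h_kg,
    gfr_fraction = rec$gfr_fraction,
    tubular_secretion_l_h = rec$tubular_secretion_l_h,
    tubular_secretion_exponent = rec$tubular_secretion_exponent %||% 0.3,
    partition_method = rec$partition_method,
    cellular_permeability_method = rec$cellular_permeability_method,
    logP_range = unlist(rec$logP_range)
  )
}

#' The packaged ofloxacin record
#'
#' @return A `drug_parameters` object for ofloxacin.
#' @export
ofloxacin <- function() {
  read_drug_parameters(extdata_path("ofloxacin.yaml"))
}

#' @export
print.drug_parameters <- function(x, ...) {
  cat("<drug_parameters>", x$name, "\n")
  cat("  MW", x$molecular_mass_g_mol, "g/mol | pKa", x$pKa_acid, "/",
      x$pKa_base, "| logP", x$logP, "| fu", x$fu, "\n")
  cat("  CL_hep", x$hepatic_clearance_l_h_kg, "L/h/kg | GFR fraction",
      x$gfr_fraction, "| tubular secretion", x$tubular_secretion_l_h, "L/h\n")
  invisible(x)
}

#' Ionization state of a diprotic zwitterion
#'
#' Henderson-Hasselbalch microspecies fractions for a molecule with one acidic
#' and one basic group: the cation (both sites protonated), the
#' zwitterion/neutral form (one proton), and the anion (fully deprotonated).
#'
#' @param pH pH value(s), each in (0, 14).
#' @param drug A `drug_parameters` object (uses `pKa_acid`, `pKa_base`).
#' @return A tibble with columns `pH`, `cation`, `zwitterion`, `anion`
#'   (fractions summing to 1 rowwise).
#' @export
fraction_species <- function(pH, drug) {
  if (any(pH <= 0 | pH >= 14)) abort("fraction_species: pH must be in (0, 14)")
  # ratios relative to the cation: successive deprotonations at pKa_acid then
  # pKa_base (carboxyl releases first in a fluoroquinolone zwitterion)
  r1 <- 10^(pH - drug$pKa_acid)
  r2 <- 10^(2 * pH - drug$pKa_acid - drug$pKa_base)
  denom <- 1 + r1 + r2
  tibble::tibble(pH = pH, cation = 1 / denom, zwitterion = r1 / denom,
                 anion = r2 / denom)
}

#' Effective unbound fraction under altered binding-protein levels
#'
#' Standard protein-ratio correction: with the binding-protein concentration
#' scaled by `protein_scaling` relative to healthy, the bound:free ratio
#' scales proportionally, so
#' `fu_eff = 1 / (1 + protein_scaling * (1 - fu) / fu)`.
#'
#' @param fu Healthy fraction unbound.
#' @param protein_scaling Binding-protein concentration ratio (healthy = 1).
#' @return Effective fraction unbound (capped at 1).
#' @export
fu_effective <- function(fu, protein_scaling = 1) {
  pmin(1, 1 / (1 + protein_scaling * (1 - fu) / fu))
}

#' Clearance decomposition for an individual
#'
#' Implements the renal clearance split into glomerular filtration and
#' tubular secretion:
#' `CL_GF = GFR_fraction * GFR_abs * fu_eff`, `CL_TS` scaled from the healthy
#' reference by `(eGFR / 110)^exponent`, `CL_R = CL_GF + CL_TS`, and hepatic
#' clearance `CL_hep = specific hepatic clearance * body weight`.
#'
#' @param drug A `drug_parameters` object.
#' @param individual A one-row individual tibble.
#' @return A one-row tibble: `fu_eff`, `CL_GF`, `CL_TS`, `CL_R`, `CL_hep`,
#'   `CL_total` (all clearances in L/h).
#' @export
clearance_terms <- function(drug, individual) {
  if (individual$gfr_abs_l_h < 0) abort("clearance_terms: negative GFR")
  fu_eff <- fu_effective(drug$fu, individual$protein_scaling)
  cl_gf <- drug$gfr_fraction * individual$gfr_abs_l_h * fu_eff
  cl_ts <- drug$tubular_secretion_l_h *
    (individual$egfr / HEALTHY_EGFR)^drug$tubular_secretion_exponent
  cl_hep <- drug$hepatic_clearance_l_h_kg * individual$weight
  tibble::tibble(
    fu_eff = fu_eff, CL_GF = cl_gf, CL_TS = cl_ts, CL_R = cl_gf + cl_ts,
    CL_hep = cl_hep, CL_total = cl_gf + cl_ts + cl_hep
  )
}
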