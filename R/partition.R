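# Mechanistic tissue:plasma partition coefficients (Rodgers-Rowland style):
# water partitioning weighted by ionization, neutral lipid / phospholipid
# partitioning of the un-ionized species, association of the base-protonated
# species with tissue acidic phospholipids, and a binding-protein term
# calibrated against the plasma fraction unbound.

PH_PLASMA <- 7.4
PH_INTRACELL <- 7.0

# Scale bridging the software-convention acidic-phospholipid association
# constant (ka_ap, dimensionless) and the composition table's mg/g acidic
# phospholipid content. For a zwitterion the base-protonated pool is mostly
# the net-neutral zwitterion, which associates far more weakly than a true
# cation; the scale is calibrated once so the healthy-reference steady-state
# distribution volume of ofloxacin lands in its reported 1.2-1.5 L/kg range.
AP_ASSOC_SCALE <- 0.25

#' Standard tissue composition table
#'
#' Packaged fractional tissue composition (extra/intracellular water, neutral
#' lipid, neutral phospholipid, acidic phospholipid content, binding-protein
#' ratio) for every model organ plus plasma.
#'
#' @return A tibble, one row per organ plus a `plasma` row.
#' @export
tissue_composition <- function() {
  read_packaged_csv("tissue_composition.csv")
}

# binding capacity of one composition relative to the unbound drug in plasma
# water; X, Y are base-protonated:neutral ratios at intracellular / plasma pH
partition_capacity <- function(comp, P, X, Y, ka_ap, ka_pr) {
  ionw <- 1 + Y
  comp$f_ew +
    comp$f_iw * (1 + X) / ionw +
    ka_ap * AP_ASSOC_SCALE * comp$ap_mg_g * X / ionw +
    (P * comp$f_nl + (0.3 * P + 0.7) * comp$f_np) / ionw +
    ka_pr * comp$pr_ratio
}

#' Tissue:plasma partition coefficients
#'
#' Computes per-organ Kp from the mechanistic tissue-composition equations.
#' The default (`zwitterion_treatment = "base"`) treats the zwitterion as a
#' monoprotic base for the acidic-phospholipid association term (using the
#' basic pKa and the individual's `ka_ap`) while keeping the neutral-species
#' lipid terms; `"neutral"` switches ionization off entirely. The
#' binding-protein association constant is calibrated so that the plasma
#' capacity equals `1 / fu_eff`, which makes a hypothetical tissue with
#' plasma's own composition partition exactly 1:1.
#'
#' @param drug A `drug_parameters` object.
#' @param individual A one-row individual tibble (supplies `ka_ap` and
#'   `protein_scaling`).
#' @param zwitterion_treatment `"base"` (default) or `"neutral"`.
#' @param composition Optional replacement composition table (must contain a
#'   `plasma` row); defaults to [tissue_composition()].
#' @return A tibble with columns `organ`, `kp` (dimensionless
#'   tissue:plasma ratios, all > 0) and a `method` attribute.
#' @export
compute_partition_coefficients <- function(drug, individual,
                                           zwitterion_treatment = c("base", "neutral"),
                                           composition = NULL) {
  zwitterion_treatment <- match.arg(zwitterion_treatment)
  comp <- composition %||% tissue_composition()
  if (!"plasma" %in% comp$organ) {
    abort("composition table must contain a 'plasma' row")
  }
  plasma <- comp[comp$organ == "plasma", ]
  tissues <- comp[comp$organ != "plasma", ]

  P <- 10^drug$logP
  if (zwitterion_treatment == "base") {
    X <- 10^(drug$pKa_base - PH_INTRACELL)
    Y <- 10^(drug$pKa_base - PH_PLASMA)
  } else {
    X <- 0
    Y <- 0
  }
  fu_eff <- fu_effective(drug$fu, individual$protein_scaling)
  ka_ap <- individual$ka_ap

  # plasma capacity without the protein term; calibrate ka_pr to hit 1/fu_eff
  base_plasma <- partition_capacity(plasma, P, X, Y, ka_ap, ka_pr = 0)
  ka_pr <- max(0, 1 / fu_eff - base_plasma)
  cap_plasma <- base_plasma + ka_pr

  kp <- partition_capacity(tissues, P, X, Y, ka_ap, ka_pr) / cap_plasma
  structure(
    tibble::tibble(organ = tissues$organ, kp = kp),
    method = paste0(drug$partition_method, "/", zwitterion_treatment)
  )
}

# Kp lookup for a model organ set; errors naming any organ without a value
kp_for_organs <- function(kp_table, organs) {
  missing <- setdiff(organs, kp_table$organ)
  if (length(missing)) {
    abort(paste0("missing tissue composition / Kp for organ(s): ",
                 paste(missing, collapse = ", ")))
  }
  setNames(kp_table$kp[match(organs, kp_table$organ)], organs)
}
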