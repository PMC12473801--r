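Package: renopbpk
Title: Whole-Body PBPK Modeling of Ofloxacin in Renal Impairment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A physiologically based pharmacokinetic (PBPK) pipeline for the
    fluoroquinolone ofloxacin. Builds healthy and renally impaired virtual
    physiologies, computes mechanistic tissue-to-plasma partition coefficients
    and the glomerular-filtration/tubular-secretion clearance decomposition,
    simulates venous plasma concentration-time profiles for intravenous
    infusion and oral dosing with a whole-body perfusion-limited ODE model,
    extracts non-compartmental parameters, qualifies predictions against
    observed values with ratio, average-fold-error and error metrics, and
    derives exposure-matched dose adjustments across chronic kidney disease
    stages.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
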