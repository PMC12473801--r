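---
title: "Whole-body PBPK modeling of ofloxacin in renal impairment: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Whole-body PBPK modeling of ofloxacin in renal impairment: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(renopbpk)
```

# Scope and model overview

`renopbpk` implements a drug–disease physiologically based pharmacokinetic
(PBPK) analysis for ofloxacin, a predominantly renally cleared zwitterionic
fluoroquinolone: a whole-body simulator parameterized from the drug's
physicochemical and clearance record, extrapolated from healthy adults to
mild, moderate and severe chronic kidney disease (CKD), qualified with
non-compartmental analysis (NCA) and predicted/observed metrics, and used to
derive dose adjustments that match renally impaired exposure to healthy
exposure.

The body is represented by perfusion-limited compartments — lung in series
with the circulation, and adipose, bone, brain, gut, heart, kidney, liver,
muscle, skin, spleen and pancreas in parallel between arterial and venous
blood, with gut, spleen and pancreas draining through the liver (portal
inflow, hepatic first pass). For each tissue,

$$\frac{dA_i}{dt} = Q_i\left(C_{art} - \frac{A_i/V_i}{K_{p,i}/BP}\right),$$

with $Q_i$ the regional blood flow, $K_{p,i}$ the tissue:plasma partition
coefficient and $BP$ the blood:plasma ratio (computed from hematocrit with an
erythrocyte:plasma partition of 1, so serum and plasma are interchangeable
matrices). Renal elimination acts on arterial plasma at the kidney —
glomerular filtration physically filters incoming arterial blood — and
hepatic elimination acts on liver outflow plasma (well-stirred convention;
at ofloxacin's low hepatic extraction the distinction is numerically minor).

Oral input uses a gastric compartment emptying with first-order rate
$1/t_{GE}$ into a three-segment small-intestinal transit chain
($k_t = 3/t_{SI}$). Each segment absorbs into gut tissue at
$k_a = P_{int} \cdot A_{seg}/V_{seg}$ from the specific intestinal
permeability ($4.92\times10^{-6}$ cm/min) and a packaged geometry: 200 m²
total effective (villous-amplified) absorptive area over a 315 mL resting
lumen volume. The formulation is dissolved; solubility (2.66 mg/mL) is
checked only for a precipitation warning. These choices give a bioavailability
near 0.95, consistent with the essentially complete absorption implied by the
near-equality of the study-reported oral and intravenous clearances.

# Clearance model

Renal clearance is decomposed into glomerular filtration and tubular
secretion,

$$CL_{GF} = f_{GFR}\cdot GFR \cdot f_u, \qquad CL_{TS} = CL_R - CL_{GF},$$

with $f_{GFR} = 0.90$, $f_u = 0.90$, and the healthy-reference secretion
fixed at 5.52 L/h. Hepatic clearance is 0.04 L/h/kg times body weight.
Absolute GFR derives from the surface-normalized eGFR via
$GFR = eGFR \cdot (BSA/1.73)\cdot 0.06$ L/h, BSA by DuBois. The GFR fraction
and the unbound fraction both multiply the filtration term; with both at 0.9
the healthy 71-kg reference has $CL_R \approx 11.3$ L/h and total systemic
clearance ≈ 14.1 L/h, inside the span of the tabulated healthy predictions.

In CKD, secretion is scaled by $(eGFR/110)^{\theta}$ with default
$\theta = 0.3$. A linear-in-GFR decline ($\theta = 1$) would put severe-stage
total clearance near 3.7 L/h, well below the reported stagewise predicted
clearances (about 8.2/7.0/6.3 L/h for mild/moderate/severe); $\theta = 0.3$
is the least-squares fit of the model's predicted apparent stage clearances
to those values, and is consistent with transporter-mediated secretory
capacity declining more slowly than filtration in CKD. The exponent is
config-exposed on the drug record for sensitivity work.

# Tissue partitioning

Tissue:plasma partition coefficients follow the mechanistic
composition-based framework for ionizable drugs: extracellular and
intracellular water terms weighted by Henderson–Hasselbalch ionization
(intracellular pH 7.0, plasma pH 7.4), neutral lipid and neutral
phospholipid partitioning of the un-ionized species
($P f_{NL} + (0.3P + 0.7) f_{NP}$ with $P = 10^{\log P}$), association of
the base-protonated species with tissue acidic phospholipids, and a
binding-protein term. The protein association constant is calibrated so the
plasma binding capacity equals $1/f_u$, which makes a hypothetical tissue
with plasma's own composition partition exactly 1:1 — a symmetry the tests
assert.

Ofloxacin is diprotic (pKa 6.05 acidic, 8.22 basic). The default treatment
uses the basic pKa for the acidic-phospholipid term while retaining the
neutral-species lipid terms; a `"neutral"` switch removes ionization
entirely. Because the base-protonated pool of a zwitterion is dominated by
the net-neutral zwitterion rather than a true cation, applying the
software-convention association constant (ka 0.55 healthy, raised to 1.3 in
renal impairment) at unit scale against the mg/g composition units
overestimates tissue affinity (steady-state volume of distribution
$V_{ss} \approx 2.3$ L/kg). A fixed association scale of 0.25 is therefore
applied, calibrated once against ofloxacin's reported distribution volume
(roughly 1.0–1.5 L/kg; the model gives 1.43 L/kg for the healthy reference).
The ka elevation in renal impairment then raises $V_{ss}$ by ~15%,
prolonging the severe-stage half-life as expected.

# Physiology and CKD staging

The packaged reference physiology is an ICRP-style adult male (30 y, 73 kg,
176 cm); organ volumes scale linearly with weight, flows (and cardiac
output, defined as the sum of regional flows, keeping flow conservation
exact) with BSA. CKD stages use eGFR means 110/40/25/8 mL/min/1.73 m² with
sampling ranges 90–130, 30–50, 15–30 and 5–14 — the impaired ranges bracket
both the stage means and the creatinine clearances of the impaired study
cohorts, since the source analysis states only that populations used "a
range" of eGFR. Stage modifiers default to published CKD physiology:
hematocrit 0.42/0.38/0.33, binding-protein concentration ratio
0.96/0.92/0.86 (hypoalbuminemia, raising $f_u$ slightly for an albumin-bound
drug), gastric emptying 0.65/0.8/1.0 h (healthy 0.5 h) and small-intestinal
transit 4.2/4.6/5.0 h (healthy 3.8 h). All are overridable per call.

Populations draw demographics from truncated normals (mean, CV, hard
validity bounds), organ volumes and flows from mean-one log-normals, and
eGFR uniformly within the stage range; all sampling is seeded and
reproducible byte-for-byte.

# Numerical choices

* Solver: `deSolve::lsoda`, default `rtol 1e-8 / atol 1e-10`, fixed output
  grid of 0.05 h, with integration restarted at every dose boundary so
  infusion switches and oral boluses stay sharp. Mass balance closes to
  machine precision; the tests assert 0.1%.
* Population work (VPC ensembles, AUC distributions, dose matching) uses
  `rtol 1e-6` and a 0.2-h grid: the AUC ratios driving dose adjustment are
  insensitive to this coarsening while runs stay fast.
* NCA: linear trapezoid throughout (the likeliest match to the spreadsheet
  NCA the tables were built with; switchable design is noted in the code),
  terminal slope by best-adjusted-R² log-linear fit over the last 3–6
  post-peak points with ties resolved toward more points, apparent clearance
  `dose/AUC_0–∞` without bioavailability correction for the oral route.
  Non-decreasing tails flag the extrapolated quantities unavailable instead
  of dividing by zero.
* Dose matching: population median AUC (the source analysis is ambiguous
  between mean and median; the statistic is an argument), linear-kinetics
  proportional update with a bisection fallback, 2% relative tolerance,
  continuous dose reported plus the nearest 25-mg practical dose.

# Study designs and evaluation windows

The packaged study table carries the cohort demographics and doses of the
evaluated profiles. Settings the source tables do not print are fixed here
once: 0.5-h infusions (1 h for the 400-mg infusion study), the multiple-dose
study as 400 mg q12h for 8 doses over a 96-h horizon with AUC accumulated
over the whole horizon (which reproduces the tabulated convention of
apparent clearances well below the single-dose values), 24-h horizons for
healthy single-dose studies and 72 h for renal impairment (≈3 predicted
terminal half-lives in the severe stage). Predicted NCA parameters for the
qualification are computed on the cohort-mean individual; the
synthetic-observation module's default sampling grids are sparser
(11 points to 24 h healthy, to 48 h impaired), mimicking digitized
literature profiles.

# Synthetic observations and what passing tests show

`generate_observed()` interpolates a simulated truth at sparse times and
applies mean-one log-normal proportional noise (CV-parameterized, keeping
concentrations positive and unbiased) plus optional zero-truncated additive
noise, censoring below a 0.05 µg/mL quantification limit (censored points
are dropped, not imputed). The parameter-recovery harness compares NCA on
noisy replicates against NCA of the truth on the same sparse grid, isolating
noise effects from grid effects; at 10% proportional CV the AUC bias is well
under 1%.

The generator emulates assay/digitization scatter around a smooth truth. It
does not emulate model misspecification, inter-study heterogeneity,
absorption variability beyond the sampled physiology, or correlated
residuals — so recovery results qualify the pipeline's internal consistency,
not its fidelity to any real dataset.

# Problem sizes

Default analysis sizes used by the packaged checks: 24–40 individuals per
population for dose matching (5 seeds in the qualification suite), 200
replicates for parameter recovery, 42 predicted/observed pairs in the metric
layer. Larger cohorts (the source analysis used ~1000 virtual subjects) are
a matter of `population_spec(n = ...)` and scale linearly in runtime.

# Known limitations

* Perfusion-limited distribution only; the specific organ permeability in
  the drug record would inform a permeability-limited variant and is carried
  but unused by the solver.
* No metabolite kinetics, transporter-level secretion mechanisms,
  enterohepatic recirculation, dissolution kinetics, hemodialysis, or
  special populations beyond adult CKD.
* The exact matching criterion behind the published dose-reduction
  percentages is unprinted; the package reproduces their stage ordering and
  magnitude band, not the exact figures.
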