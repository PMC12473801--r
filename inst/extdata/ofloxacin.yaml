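# Ofloxacin baseline parameter record (zwitterionic fluoroquinolone).
# logP is the optimized point value; logP_range retains the literature span
# for sensitivity runs. Clearances follow the glomerular-filtration /
# tubular-secretion decomposition CL_R = CL_GF + CL_TS with
# CL_GF = GFR_fraction * GFR * fu.
name: ofloxacin
molecular_mass_g_mol: 361.388
pKa_acid: 6.05
pKa_base: 8.22
logP: 1.00
logP_range: [-0.39, 2.1]
fu: 0.90
binding_partner: albumin
solubility_mg_ml: 2.66
solubility_ph: 7.0
specific_intestinal_permeability_cm_min: 4.92e-06
specific_organ_permeability_cm_min: 1.29e-04
hepatic_clearance_l_h_kg: 0.04
gfr_fraction: 0.90
tubular_secretion_l_h: 5.52
tubular_secretion_exponent: 0.3
partition_method: rodgers_rowland
cellular_permeability_method: standard
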