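# Demographics and dosing schedules of the clinical studies backing the
# PRE/OBS evaluation tables. age/weight are the reported means (midpoint of
# the reported range where only a range was given); height was not reported
# and defaults to the reference adult. female_pct NA = not mentioned.
study,cohort,route,dose_mg,n_subjects,female_pct,age_y,weight_kg
lode_100,healthy,iv_infusion,100,10,50,35.5,64.0
lode_200,healthy,iv_infusion,200,10,50,35.5,64.0
flor_iv,healthy,iv_infusion,400,20,0,29.5,80.5
stein_200a,healthy,oral,200,32,0,27.5,79.0
stein_200b,healthy,oral,200,32,0,27.5,79.0
stein_300a,healthy,oral,300,32,0,27.5,79.0
stein_300b,healthy,oral,300,32,0,27.5,79.0
sanchez_400,healthy,oral,400,10,20,35.5,62.3
molinaro_300,healthy,oral,300,12,0,23.5,74.0
fillastre_200,healthy,oral,200,12,NA,27.7,71.0
flor_po,healthy,oral,400,20,0,29.5,80.5
fillastre_mild,mild,oral,200,12,NA,58.0,63.6
fillastre_moderate,moderate,oral,200,12,NA,63.3,72.4
fillastre_severe,severe,oral,200,12,NA,63.6,74.4
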