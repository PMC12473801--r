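# Predicted (PRE) and observed (OBS) NCA parameters for the healthy cohorts:
# Cmax (ug/mL), AUC_0-t (ug*h/mL), CL (L/h). One row per study profile.
study,route,dose_mg,cmax_pre,cmax_obs,auc_pre,auc_obs,cl_pre,cl_obs
lode_100,iv_infusion,100,2.39,2.70,7.94,7.19,12.16,13.19
lode_200,iv_infusion,200,4.78,4.98,15.81,14.47,12.21,13.23
flor_iv,iv_infusion,400,7.74,6.92,253.68,152.05,1.56,2.52
stein_200a,oral,200,2.33,1.66,16.07,14.39,12.30,13.71
stein_200b,oral,200,2.33,2.11,16.08,15.24,12.29,12.87
stein_300a,oral,300,3.46,2.41,22.70,20.20,13.20,14.67
stein_300b,oral,300,3.46,3.08,23.06,20.79,12.83,14.24
sanchez_400,oral,400,4.64,3.31,27.90,29.49,12.99,12.00
molinaro_300,oral,300,3.19,2.30,20.57,18.99,12.99,15.07
fillastre_200,oral,200,2.25,2.00,13.77,10.42,12.95,16.98
flor_po,oral,400,5.25,5.36,118.30,160.16,3.26,2.36
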