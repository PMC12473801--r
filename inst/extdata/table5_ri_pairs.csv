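# Predicted (PRE) and observed (OBS) NCA parameters for the renally impaired
# cohorts (oral 200 mg): Cmax (ug/mL), AUC_0-t (ug*h/mL), CL (L/h).
study,stage,dose_mg,cmax_pre,cmax_obs,auc_pre,auc_obs,cl_pre,cl_obs
fillastre_mild,mild,200,1.91,1.52,22.32,28.79,8.16,5.88
fillastre_moderate,moderate,200,1.59,1.55,25.50,34.33,7.01,4.90
fillastre_severe,severe,200,1.64,1.57,31.49,50.12,6.32,3.46
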