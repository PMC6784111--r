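antibody,dose_mg_per_kg,C0a_mg_per_L,C0b_mg_per_L,t_half_beta_h,AUC_0_144_mg_h_per_L,CL_mL_h_kg,VDss_mL_kg
2-DIQMAQ-K,5,NA,NA,NA,NA,NA,NA
2-DIQMAQ-K,15,6.0,3.7,34.5,209.6,72,3067
2-DIQMAQ-K,30,15.6,5.0,37.9,326.8,98,3757
9-EIVLGE,5,29.7,14.0,135.9,1873.6,3.5,170
9-EIVLGE,15,76.4,45.1,96.3,5036.7,3.2,160
9-EIVLGE,30,149.1,55.2,87.7,6611.3,3.6,190
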