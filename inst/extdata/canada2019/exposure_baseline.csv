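sex,dri_group,mean_kcal,se_kcal,mean_bmi,sd_bmi,mean_height_m,n_survey
male,19-30,2023,44,25.69,5.0,1.76,882
male,31-50,2037,26,28.41,5.0,1.76,2077
male,51-70,2054,29,28.98,5.0,1.74,2246
male,71+,2091,26,27.96,5.0,1.72,1246
female,19-30,1515,35,25.02,5.0,1.64,897
female,31-50,1567,22,26.72,5.0,1.63,2288
female,51-70,1642,19,27.74,5.0,1.61,2420
female,71+,1658,24,27.35,5.0,1.58,1556
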