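quantity,value
mean_free_sugars_g_day_baseline,56.2
mean_kcal_day_baseline,1858
mean_kcal_day_counterfactual,1798
mean_kcal_reduction,60
reduction_fraction,0.2
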