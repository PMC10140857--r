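id,sex,actual
cardiovascular,both,55662
cardiovascular,male,29219
cardiovascular,female,26443
diabetes,both,6536
diabetes,male,3664
diabetes,female,2872
cancer,both,22060
cancer,male,8777
cancer,female,13283
renal,both,2118
renal,male,1102
renal,female,1016
liver,both,3659
liver,male,2364
liver,female,1295
total,both,90035
total,male,45126
total,female,44909
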