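level,id,group,sex,averted,ui_lo,ui_hi
group,cardiovascular,cardiovascular,both,4491,3999,4953
group,cardiovascular,cardiovascular,male,2500,2250,2742
group,cardiovascular,cardiovascular,female,2000,1648,2313
cause,ihd,cardiovascular,both,2392,2055,2695
cause,ihd,cardiovascular,male,1593,1401,1774
cause,ihd,cardiovascular,female,806,534,1047
cause,stroke,cardiovascular,both,791,555,1021
cause,stroke,cardiovascular,male,341,241,438
cause,stroke,cardiovascular,female,452,308,585
cause,heart_failure,cardiovascular,both,766,480,978
cause,heart_failure,cardiovascular,male,338,209,435
cause,heart_failure,cardiovascular,female,426,258,539
cause,hypertensive,cardiovascular,both,559,432,636
cause,hypertensive,cardiovascular,male,234,184,267
cause,hypertensive,cardiovascular,female,327,253,371
group,diabetes,diabetes,both,954,734,1083
group,diabetes,diabetes,male,528,414,598
group,diabetes,diabetes,female,429,329,488
group,cancer,cancer,both,781,609,958
group,cancer,cancer,male,351,265,435
group,cancer,cancer,female,431,339,520
cause,pancreas,cancer,both,140,28,256
cause,pancreas,cancer,male,71,13,126
cause,pancreas,cancer,female,69,13,124
cause,colorectum,cancer,both,357,236,470
cause,colorectum,cancer,male,191,130,251
cause,colorectum,cancer,female,165,111,218
cause,breast,cancer,both,37,-9,82
cause,breast,cancer,male,0,0,0
cause,breast,cancer,female,38,-6,83
cause,endometrium,cancer,both,103,76,124
cause,endometrium,cancer,male,0,0,0
cause,endometrium,cancer,female,103,76,124
cause,gallbladder,cancer,both,14,10,19
cause,gallbladder,cancer,male,5,4,7
cause,gallbladder,cancer,female,9,6,12
cause,kidney,cancer,both,131,105,156
cause,kidney,cancer,male,84,67,100
cause,kidney,cancer,female,47,38,56
group,renal,renal,both,218,85,307
group,renal,renal,male,109,48,156
group,renal,renal,female,107,45,151
group,liver,liver,both,351,188,471
group,liver,liver,male,227,127,303
group,liver,liver,female,124,59,171
under_75,under_75,,both,2293,2092,2483
under_75,under_75,,male,1545,1415,1661
under_75,under_75,,female,752,659,834
total,total,,both,6770,6184,7333
total,total,,male,3704,3394,3988
total,total,,female,3082,2692,3429
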