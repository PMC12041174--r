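source,patient_id,scenario,cha0_ml_min,gda0_ml_min,pha0_ml_min,real_post_ml_min,predicted_post_ml_min,interval_min_ml_min,interval_max_ml_min,printed_error_pct,printed_rel_error_min_pct,error_consistent,rel_error_min_consistent
Table 1,ID16,clamp_GDA,331,60,271,314,289.2,247.1,331.3,8,21,TRUE,TRUE
Table 1,ID17,clamp_GDA,144,18,126,120,129.6,112.5,146.7,5,6,FALSE,TRUE
Table 1,ID18,clamp_GDA,179,52,127,136,130.8,105.1,156.6,4,22,TRUE,FALSE
Table 1,ID19,clamp_GDA,215,54,161,153,171.6,142.3,201.2,3,7,FALSE,TRUE
Table 1,ID20,clamp_GDA,213,67,146,176,159.6,128.25,190.95,9,27,TRUE,TRUE
Table 2,ID16,clamp_CHA,331,60,271,91,103.2,89.72,118.7,13.1,NA,FALSE,NA
Table 2,ID17,clamp_CHA,144,18,126,43,47.5,42.9,51.06,10.4,NA,FALSE,NA
Table 2,ID18,clamp_CHA,179,52,127,203,74.5,68.9,80.86,3.3,NA,FALSE,NA
Table 2,ID19,clamp_CHA,215,54,161,98,102.3,94.3,109.9,4.1,NA,FALSE,NA
Table 2,ID20,clamp_CHA,213,67,146,99,106.2,98.2,114.1,8.1,NA,FALSE,NA
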