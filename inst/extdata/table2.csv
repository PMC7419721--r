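filter,va_mean,va_sd,va_rel,va_sig,cr_mean,cr_sd,cr_rel,cr_sig,stereo_mean,stereo_sd,stereo_rel,stereo_sig
baseline,0.02,0.04,1,FALSE,1.44,0.32,1,FALSE,40,16,1,FALSE
0.8,0.12,0.10,6,TRUE,1.49,0.41,1,FALSE,40,17,1,FALSE
0.6,0.29,0.10,14.5,TRUE,1.87,0.93,1.3,FALSE,41,17,1,FALSE
0.4,0.48,0.16,24,TRUE,2.44,1.08,1.7,TRUE,48,14,1.2,FALSE
0.1,0.54,0.09,27,TRUE,3.64,1.59,2.5,TRUE,46,14,1.2,FALSE
<0.1,0.97,0.12,48.5,TRUE,9.84,8.71,6.8,TRUE,88,36,2.2,TRUE
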