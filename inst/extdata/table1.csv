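decrement_pct,stereo_mean,stereo_sd,relative_change,significant
0,40,16,1,FALSE
10,57,22,1.4,TRUE
20,132,212,5.3,TRUE
30,512,750,12.8,TRUE
40,1780,1360,44.5,TRUE
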