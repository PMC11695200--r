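characteristic,mean_case,sd_case,n_case,mean_control,sd_control,n_control,test
age,59.17,6.85,66,57.83,6.52,54,pooled
education,10.94,1.74,66,10.87,1.71,54,pooled
pta_left,32.82,4.22,66,16.00,2.81,54,welch
pta_right,33.05,6.09,66,16.13,3.23,54,welch
pta_mean,32.93,3.85,66,16.06,2.27,54,welch
mmse,28.76,1.14,66,28.89,1.14,54,pooled
moca,26.30,1.86,66,26.83,1.40,54,welch
tmt_a,74.48,23.34,66,65.24,18.68,54,welch
tmt_b,172.55,51.06,66,151.11,47.66,54,pooled
dst,11.00,1.57,66,11.78,2.01,54,pooled
dsst,69.06,7.75,66,68.78,9.48,54,welch
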