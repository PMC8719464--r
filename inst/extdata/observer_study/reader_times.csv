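reader,mean_unaided,mean_aided,difference,p_value,n_time_increase,n_time_decrease,n_time_same
1,55.27,55.51,0.24,0.955,22,29,0
2,80.59,81.18,0.59,0.912,12,38,1
3,63.90,64.24,0.34,0.928,22,27,2
4,45.10,42.59,-2.51,0.378,9,39,3
5,42.35,37.35,-5,0.089,14,36,1
6,56.96,43.96,-13,0.001,19,32,0
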