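reader,n_increase,n_decrease,n_closer_to_biopsy,n_not_matching
1,14,4,10,8
2,11,15,15,11
3,11,13,13,11
4,17,5,8,14
5,22,4,14,12
6,5,7,7,5
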