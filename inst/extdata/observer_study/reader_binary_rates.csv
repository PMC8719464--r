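reader,sens_unaided,sens_aided,spec_unaided,spec_aided,ppv_unaided,ppv_aided,npv_unaided,npv_aided
1,0.545,0.682,0.931,0.931,0.857,0.882,0.729,0.794
2,0.682,0.864,0.621,0.621,0.577,0.633,0.720,0.857
3,0.773,0.773,0.793,0.897,0.739,0.850,0.821,0.838
4,0.773,0.864,0.862,0.931,0.810,0.905,0.833,0.900
5,0.819,0.901,0.793,0.689,0.750,0.689,0.851,0.909
6,0.773,0.773,0.863,0.897,0.809,0.850,0.833,0.838
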