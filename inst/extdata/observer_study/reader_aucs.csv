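reader,auc_unaided,auc_aided
1,0.842,0.920
2,0.783,0.892
3,0.889,0.922
4,0.852,0.890
5,0.866,0.904
6,0.869,0.847
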