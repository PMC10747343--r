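time_h,fraction_dissolved
0,0
0.083,0.42
0.167,0.64
0.25,0.76
0.5,0.9
0.75,0.95
1,0.97
2,1
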