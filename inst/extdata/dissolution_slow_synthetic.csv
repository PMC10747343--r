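time_h,fraction_dissolved
0,0
0.25,0.14
0.5,0.26
1,0.42
1.5,0.52
2,0.6
3,0.68
4,0.74
6,0.82
8,0.87
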