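threshold,precision_reported
0.10,0.67
0.15,0.73
0.20,0.75
0.25,0.74
0.30,0.75
0.35,0.75
0.40,0.64
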