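threshold,true_count,false_count
0.10,173,66
0.15,167,61
0.20,145,48
0.25,98,33
0.30,54,18
0.35,27,9
0.40,11,6
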