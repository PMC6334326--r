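factor,side,mean_altered,mean_nominal,deviation
A,-1,100.49,100.20,0.29
A,1,100.84,100.22,0.62
B,-1,100.66,100.03,0.63
B,1,100.02,101.04,1.03
C,-1,100.35,100.34,0.01
C,1,100.62,100.44,0.17
D,-1,100.31,100.39,0.08
D,1,101.03,100.03,1.01
E,-1,100.68,100.02,0.66
E,1,100.49,100.57,0.08
F,-1,101.23,100.46,0.23
F,1,100.73,100.33,0.40
G,-1,100.15,100.54,0.40
G,1,100.23,100.82,0.59
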