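factor,side,deviation
A,1,0.62
B,1,1.03
C,1,0.17
D,1,1.01
E,1,0.08
F,1,0.40
G,1,0.59
A,-1,0.29
B,-1,0.63
C,-1,0.01
D,-1,0.08
E,-1,0.66
F,-1,0.23
G,-1,0.40
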