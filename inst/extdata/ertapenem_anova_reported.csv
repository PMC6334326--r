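source,ms,f,f_crit
between-concentration,5469600032.01,1993.04,3.11
linear regression,27315622241.54,9953.42,4.75
deviation of linearity,8094479.63,2.95,3.26
residue,2744346.59,,
total,,,
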