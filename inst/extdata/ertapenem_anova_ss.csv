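source,df,ss
between-concentration,5,27348000160.07
linear regression,1,27315622241.54
deviation of linearity,4,32377918.53
residue,12,32932159.12
total,17,27380932319.19
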