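run,corrected_area,apex_time,plate_number,asymmetry
1,200747,3.17,11120,0.85
2,206731,3.20,10947,0.83
3,206201,3.19,11045,0.84
4,205646,3.19,10895,0.85
5,203986,3.19,10824,0.84
6,205936,3.21,10624,0.84
7,207729,3.23,10537,0.85
8,200253,3.23,11046,0.84
9,205686,3.23,10782,0.84
10,204768,3.20,10868,0.84
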