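age,p2.5,p10,p25,p50,p75,p90
7,0,4,7,10,13,16
8,2,5,8,12,16,18
9,4,8,11,15,18,22
10,7,10,14,18,21,24
11,10,13,17,20,23,26
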