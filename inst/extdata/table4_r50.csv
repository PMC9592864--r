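case,r50_pct
P10,0.10
P12,1.78
P13,42.20
P14,3.52
P15,56.44
P17,46.10
P18,41.34
P19,78.13
P21,4.27
P22,0.00
P24,38.34
P25,20.65
P26,0.61
P27,6.54
P28,77.64
P29,3.18
P30,56.47
P31,47.29
P32,2.33
P33,56.90
P34,57.98
P35,93.14
P36,36.67
P37,84.93
P38,1.76
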