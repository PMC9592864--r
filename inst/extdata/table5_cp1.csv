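case,marker,cp1
P10,Bim,-1.208
P12,Bim,-2.795
P13,Bim,-1.187
P14,Bim,0.263
P15,Bim,0.479
P17,Bim,0.296
P18,Bim,-1.237
P19,Bim,2.22
P21,Bim,-1.148
P22,Bim,0.384
P24,Bim,0.54
P25,Bim,1.433
P26,Bim,-1.065
P27,Bim,0.924
P28,Bim,1.844
P29,Bim,-1.483
P30,Bim,2.375
P31,Bim,0.535
P32,Bim,-2.157
P33,Bim,0.249
P34,Bim,1.167
P35,Bim,-1.68
P36,Bim,1.191
P37,Bim,-0.78
P38,Bim,0.841
P10,Mcl-1,-2.74
P12,Mcl-1,-1.47
P13,Mcl-1,-0.25
P14,Mcl-1,0.928
P15,Mcl-1,-0.989
P17,Mcl-1,1.92
P18,Mcl-1,-0.216
P19,Mcl-1,1.648
P21,Mcl-1,-0.498
P22,Mcl-1,0.449
P24,Mcl-1,-0.217
P25,Mcl-1,2.683
P26,Mcl-1,0.456
P27,Mcl-1,-0.553
P28,Mcl-1,1.559
P29,Mcl-1,-1.653
P30,Mcl-1,0.927
P31,Mcl-1,-1.271
P32,Mcl-1,-1.18
P33,Mcl-1,0.128
P34,Mcl-1,1.948
P35,Mcl-1,-0.936
P36,Mcl-1,0.049
P37,Mcl-1,-0.96
P38,Mcl-1,0.238
P10,P-ERK,-4.08
P12,P-ERK,-0.951
P13,P-ERK,0.228
P14,P-ERK,-0.23
P15,P-ERK,1.064
P17,P-ERK,1.623
P18,P-ERK,0.255
P19,P-ERK,1.301
P21,P-ERK,-2.894
P22,P-ERK,0.123
P24,P-ERK,-0.429
P25,P-ERK,-1.051
P26,P-ERK,-1.419
P27,P-ERK,-0.588
P28,P-ERK,1.184
P29,P-ERK,-0.241
P30,P-ERK,0.886
P31,P-ERK,0.769
P32,P-ERK,0.052
P33,P-ERK,0.56
P34,P-ERK,0.617
P35,P-ERK,2.13
P36,P-ERK,-0.173
P37,P-ERK,1.513
P38,P-ERK,-0.248
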