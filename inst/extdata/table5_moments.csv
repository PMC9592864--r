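case,marker,i_moy,i_sig,i_skw
P10,Bim,0.37,0.035,0.178
P12,Bim,0.312,0.025,0.679
P13,Bim,0.335,0.04,0.208
P14,Bim,0.476,0.044,0.129
P15,Bim,0.531,0.039,0.097
P17,Bim,0.435,0.058,0.642
P18,Bim,0.414,0.033,0.488
P19,Bim,0.561,0.055,-0.447
P21,Bim,0.42,0.037,0.666
P22,Bim,0.515,0.04,0.103
P24,Bim,0.525,0.048,0.501
P25,Bim,0.508,0.054,-0.155
P26,Bim,0.425,0.036,0.594
P27,Bim,0.449,0.053,-0.204
P28,Bim,0.556,0.039,-1.087
P29,Bim,0.425,0.042,1.374
P30,Bim,0.588,0.064,0.18
P31,Bim,0.452,0.042,-0.461
P32,Bim,0.344,0.036,0.988
P33,Bim,0.494,0.045,0.391
P34,Bim,0.464,0.056,-0.157
P35,Bim,0.379,0.029,0.41
P36,Bim,0.588,0.046,0.236
P37,Bim,0.426,0.036,0.303
P38,Bim,0.445,0.05,-0.319
P10,Mcl-1,0.316,0.026,1.307
P12,Mcl-1,0.36,0.035,1.193
P13,Mcl-1,0.402,0.037,0.738
P14,Mcl-1,0.449,0.041,0.483
P15,Mcl-1,0.411,0.034,1.235
P17,Mcl-1,0.404,0.064,0.434
P18,Mcl-1,0.47,0.04,1.467
P19,Mcl-1,0.471,0.048,0.481
P21,Mcl-1,0.406,0.034,0.81
P22,Mcl-1,0.465,0.04,0.923
P24,Mcl-1,0.384,0.039,0.626
P25,Mcl-1,0.494,0.047,-0.13
P26,Mcl-1,0.45,0.036,0.616
P27,Mcl-1,0.436,0.03,0.97
P28,Mcl-1,0.512,0.038,0.425
P29,Mcl-1,0.363,0.036,1.405
P30,Mcl-1,0.425,0.035,-0.033
P31,Mcl-1,0.397,0.033,1.297
P32,Mcl-1,0.361,0.033,0.865
P33,Mcl-1,0.405,0.051,1.153
P34,Mcl-1,0.41,0.058,0.185
P35,Mcl-1,0.426,0.032,1.251
P36,Mcl-1,0.452,0.042,1.242
P37,Mcl-1,0.427,0.034,1.364
P38,Mcl-1,0.422,0.031,0.294
P10,P-ERK,0.009,0.055,6.372
P12,P-ERK,0.185,0.188,0.083
P13,P-ERK,0.356,0.227,-0.711
P14,P-ERK,0.269,0.172,-0.798
P15,P-ERK,0.423,0.146,-2.325
P17,P-ERK,0.449,0.069,-3.731
P18,P-ERK,0.344,0.205,-1.021
P19,P-ERK,0.477,0.168,-2.162
P21,P-ERK,0.033,0.121,3.374
P22,P-ERK,0.39,0.03,-0.278
P24,P-ERK,0.267,0.25,-0.083
P25,P-ERK,0.188,0.234,0.505
P26,P-ERK,0.131,0.172,0.606
P27,P-ERK,0.235,0.21,-0.184
P28,P-ERK,0.46,0.169,-2.072
P29,P-ERK,0.268,0.178,-0.763
P30,P-ERK,0.432,0.176,-1.596
P31,P-ERK,0.398,0.169,-1.781
P32,P-ERK,0.298,0.161,-1.217
P33,P-ERK,0.39,0.205,-1.225
P34,P-ERK,0.407,0.219,-1.106
P35,P-ERK,0.531,0.093,-3.931
P36,P-ERK,0.296,0.231,-0.444
P37,P-ERK,0.469,0.133,-2.982
P38,P-ERK,0.269,0.184,-0.729
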