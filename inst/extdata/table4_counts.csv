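case,marker,n0,n1,n2,ip_label,expert_label
P10,Bim,198,770,0,high,high
P12,Bim,1204,162,0,low,low
P13,Bim,512,415,0,low,low
P14,Bim,0,366,143,high,high
P15,Bim,0,92,338,high,high
P17,Bim,0,8,2,high,high
P18,Bim,5,649,9,high,high
P19,Bim,0,42,297,high,high
P21,Bim,10,1410,38,high,high
P22,Bim,0,49,77,high,high
P24,Bim,0,795,1367,high,high
P25,Bim,2,707,942,high,high
P26,Bim,0,1791,58,high,low
P27,Bim,27,849,175,high,high
P28,Bim,0,60,768,high,high
P29,Bim,4,2129,114,high,low
P30,Bim,0,30,315,high,high
P31,Bim,22,2107,240,high,high
P32,Bim,711,636,4,low,high
P33,Bim,0,976,703,high,high
P34,Bim,13,563,206,high,high
P35,Bim,36,369,1,high,low
P36,Bim,0,38,1603,high,high
P37,Bim,7,2086,64,high,high
P38,Bim,20,492,75,high,high
P10,Mcl-1,919,36,2,low,low
P12,Mcl-1,653,246,37,low,high
P13,Mcl-1,111,466,94,high,high
P14,Mcl-1,9,193,227,high,high
P15,Mcl-1,36,374,77,high,high
P17,Mcl-1,71,53,54,low,high
P18,Mcl-1,3,137,715,high,high
P19,Mcl-1,2,92,261,high,high
P21,Mcl-1,157,1005,209,high,low
P22,Mcl-1,0,61,146,high,high
P24,Mcl-1,784,807,181,high,low
P25,Mcl-1,8,253,1664,high,high
P26,Mcl-1,3,1007,1202,high,low
P27,Mcl-1,10,513,391,high,high
P28,Mcl-1,0,9,801,high,high
P29,Mcl-1,1231,634,62,low,low
P30,Mcl-1,21,291,136,high,high
P31,Mcl-1,410,1735,199,high,low
P32,Mcl-1,654,301,22,low,low
P33,Mcl-1,295,595,239,high,low
P34,Mcl-1,177,279,207,high,high
P35,Mcl-1,3,338,92,high,low
P36,Mcl-1,1,948,1221,high,high
P37,Mcl-1,32,1579,578,high,high
P38,Mcl-1,27,416,162,high,high
P10,P-ERK,949,20,1,low,low
P12,P-ERK,589,514,20,low,low
P13,P-ERK,278,322,438,low,low
P14,P-ERK,210,420,23,low,low
P15,P-ERK,52,178,298,high,low
P17,P-ERK,2,74,65,low,high
P18,P-ERK,207,264,332,low,high
P19,P-ERK,44,52,343,high,high
P21,P-ERK,1284,40,59,low,low
P22,P-ERK,0,30,0,low,high
P24,P-ERK,896,302,745,low,low
P25,P-ERK,1225,389,420,low,low
P26,P-ERK,1112,529,10,low,low
P27,P-ERK,593,664,88,low,low
P28,P-ERK,103,107,729,high,low
P29,P-ERK,577,1250,60,low,low
P30,P-ERK,57,138,253,high,low
P31,P-ERK,275,716,889,low,low
P32,P-ERK,263,910,28,low,low
P33,P-ERK,348,380,961,high,low
P34,P-ERK,196,199,545,high,high
P35,P-ERK,9,19,380,high,high
P36,P-ERK,942,654,924,low,low
P37,P-ERK,201,228,2417,high,high
P38,P-ERK,488,1019,27,low,low
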