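marker,case,comparison,sensitivity_pct,specificity_pct,quality_factor_pct
Bim,P15,Expert2,70.90,94.59,82.75
Bim,P15,IP_OHTA,54.44,90.48,72.46
Bim,P18,Expert2,85.79,66.22,76.01
Bim,P18,IP_OHTA,82.62,62.28,72.45
Bim,P26,Expert2,92.94,49.40,71.17
Bim,P26,IP_OHTA,89.82,55.77,72.80
Mcl-1,P25,Expert2,70.90,94.59,82.75
Mcl-1,P25,IP_OHTA,54.44,90.48,72.46
Mcl-1,P29,Expert2,85.79,66.22,76.01
Mcl-1,P29,IP_OHTA,82.62,62.28,72.45
Mcl-1,P37,Expert2,92.94,49.40,71.17
Mcl-1,P37,IP_OHTA,89.82,55.77,72.80
P-ERK,P19,Expert2,97.85,92.05,94.95
P-ERK,P19,IP_OHTA,89.43,75.86,82.65
P-ERK,P26,Expert2,99.39,77.05,88.22
P-ERK,P26,IP_OHTA,98.64,45.71,72.18
P-ERK,P36,Expert2,96.67,82.64,89.66
P-ERK,P36,IP_OHTA,91.52,80.85,86.19
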