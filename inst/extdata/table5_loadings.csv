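marker,i_moy_pct,i_sig_pct,i_skw_pct
Bim,63.68,57.65,-51.20
Mcl-1,-54.58,-56.24,62.11
P-ERK,70.51,3.84,-70.81
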