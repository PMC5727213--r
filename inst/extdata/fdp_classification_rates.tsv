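compound	original_pct	cv_pct
methyl_butanoate	95.8	95.8
ethyl_butanoate	100.0	95.8
methyl_hexanoate	87.5	87.5
ethyl_hexanoate	95.8	95.8
mesifuranne	100.0	100.0
linalool	83.3	79.2
e_nerolidol	95.8	95.8
g_dodecalactone	100.0	87.5
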