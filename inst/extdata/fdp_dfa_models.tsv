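compound	feature
methyl_butanoate	FaP1E7MB
methyl_butanoate	FaP1D7
ethyl_butanoate	FaP1D11
ethyl_butanoate	FaP3B9
ethyl_butanoate	FaP3A2
methyl_hexanoate	FaP2A11
methyl_hexanoate	FaP1E7MH
ethyl_hexanoate	FaP1B3
ethyl_hexanoate	FaP1G2
mesifuranne	FaP2G4
mesifuranne	FaP2E6
mesifuranne	FaP3H11
linalool	FaP3E12
e_nerolidol	FaP2D11
e_nerolidol	FaP1G8
e_nerolidol	FaP3F10
g_dodecalactone	FaP2E1
g_dodecalactone	FaP1A7
g_dodecalactone	FaP3F8
g_dodecalactone	FaP3E8
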