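compound	rank	feature
methyl_butanoate	1	FaP1C8
methyl_butanoate	2	FaP1A4
methyl_butanoate	3	FaP1A10
methyl_butanoate	4	FaP1E11
methyl_butanoate	5	FaP1D7
methyl_butanoate	6	FaP1F1
methyl_butanoate	7	FaP1E1
methyl_butanoate	8	FaP2D7
methyl_butanoate	9	FaP2F4
methyl_butanoate	10	FaP2B5
ethyl_butanoate	1	FaP3C12
ethyl_butanoate	2	FaP4D1
ethyl_butanoate	3	FaP1F12
ethyl_butanoate	4	FaP3E8
ethyl_butanoate	5	FaP2C2
ethyl_butanoate	6	FaP1D11
ethyl_butanoate	7	FaP4C4
ethyl_butanoate	8	FaP3C7
ethyl_butanoate	9	FaP1C6
ethyl_butanoate	10	FaP2F8
methyl_hexanoate	1	FaP3H11
methyl_hexanoate	2	FaP4B10
methyl_hexanoate	3	FaP4C4
methyl_hexanoate	4	FaP3C12
methyl_hexanoate	5	FaP3E11
methyl_hexanoate	6	FaP4D6
methyl_hexanoate	7	FaP3F4
methyl_hexanoate	8	FaP2H3
methyl_hexanoate	9	FaP4A3
methyl_hexanoate	10	FaP3D10
ethyl_hexanoate	1	FaP2B5
ethyl_hexanoate	2	FaP2B8
ethyl_hexanoate	3	FaP1B3
ethyl_hexanoate	4	FaP4B3
ethyl_hexanoate	5	FaP2E3
ethyl_hexanoate	6	FaP2B1
ethyl_hexanoate	7	FaP1D7
ethyl_hexanoate	8	FaP3G10
ethyl_hexanoate	9	FaP2C6
ethyl_hexanoate	10	FaP3F4
mesifuranne	1	FaP1H10
mesifuranne	2	FaP2G5
mesifuranne	3	FaP2E2
mesifuranne	4	FaP3F8
mesifuranne	5	FaP1H5
mesifuranne	6	FaP4C11
mesifuranne	7	FaP2F3
mesifuranne	8	FaP1H8
mesifuranne	9	FaP1E11
mesifuranne	10	FaP1D5
linalool	1	FaP2F6
linalool	2	FaP1D1
linalool	3	FaP1C11
linalool	4	FaP4A8
linalool	5	FaP3E11
linalool	6	FaP1B3
linalool	7	FaP3E12
linalool	8	FaP2F12
linalool	9	FaP1C1
linalool	10	FaP2B3
e_nerolidol	1	FaP2D4
e_nerolidol	2	FaP2E3
e_nerolidol	3	FaP2B1
e_nerolidol	4	FaP2A12
e_nerolidol	5	FaP1B3
e_nerolidol	6	FaP2D11
e_nerolidol	7	FaP1B5
e_nerolidol	8	FaP2D9
e_nerolidol	9	FaP1D1
e_nerolidol	10	FaP3F2
g_dodecalactone	1	FaP1A7
g_dodecalactone	2	FaP1G9
g_dodecalactone	3	FaP1H3
g_dodecalactone	4	FaP1G8
g_dodecalactone	5	FaP1D1
g_dodecalactone	6	FaP4C11
g_dodecalactone	7	FaP4C8
g_dodecalactone	8	FaP1G6
g_dodecalactone	9	FaP4B6
g_dodecalactone	10	FaP4D4
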