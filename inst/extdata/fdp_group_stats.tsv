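compound	feature	mean_H	sd_H	mean_L	sd_L	n_H	n_L	t_printed	df_printed	signif_printed	variant_printed
methyl_butanoate	FaP1D7	248.23	84.05	578.61	291.75	12	12	-3.77	12.8	**	welch
methyl_butanoate	FaP1E7MB	242.69	91.59	192.24	97.77	12	12	1.31	22	ns	pooled
ethyl_butanoate	FaP1D11	279.03	85.56	1333.86	541.59	12	12	-6.66	11.6	**	welch
ethyl_butanoate	FaP3A2	81.80	16.68	180.47	72.65	12	12	-4.59	12.2	**	welch
ethyl_butanoate	FaP3B9	17.72	4.95	35.11	16.73	12	12	-3.45	12.9	**	welch
methyl_hexanoate	FaP1E7MH	13.48	6.31	136.56	95.59	12	12	-4.45	11.1	**	welch
methyl_hexanoate	FaP2A11	96.35	48.97	151.74	111.30	12	12	-1.58	15.1	ns	welch
ethyl_hexanoate	FaP1B3	44.43	14.18	142.83	35.33	12	12	-8.95	14.5	**	welch
ethyl_hexanoate	FaP1G2	340.87	113.77	640.48	293.72	12	12	-3.30	14.2	**	welch
mesifuranne	FaP2E6	90.28	26.69	18.70	8.90	12	12	8.81	13.4	**	welch
mesifuranne	FaP2G4	78.51	53.40	64.81	18.80	12	12	0.84	22	ns	pooled
mesifuranne	FaP3H11	34.96	12.62	37.67	15.79	12	12	-0.47	22	ns	pooled
linalool	FaP3E12	884.13	521.74	226.77	218.23	12	12	4.03	14.7	**	welch
e_nerolidol	FaP1G8	684.26	421.21	807.65	535.49	12	12	-0.63	22	ns	pooled
e_nerolidol	FaP2D11	493.63	156.16	303.39	130.25	12	12	3.24	22	**	pooled
e_nerolidol	FaP3F10	448.95	276.61	274.31	155.03	12	12	1.91	17.3	ns	welch
g_dodecalactone	FaP1A7	282.66	119.63	106.71	57.26	12	12	4.60	22	**	pooled
g_dodecalactone	FaP2E1	1451.21	887.38	795.11	989.51	12	12	1.71	22	ns	pooled
g_dodecalactone	FaP3E8	317.99	214.62	314.93	224.38	12	12	0.03	22	ns	pooled
g_dodecalactone	FaP3F8	175.01	132.88	223.85	468.06	12	12	-0.35	22	ns	pooled
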