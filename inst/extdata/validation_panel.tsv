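# FaP1D7 C/T marker validation panel: F1 extremes carry published methyl
# butanoate levels; the six commercial-cultivar levels are synthetic
# stand-ins evenly spaced within the published 3.9-5.6% range.
genotype	allele	methyl_butanoate_pct	class
P1	C	0.0	F1_low
P63	T	0.0	F1_low
P38	T	24.1	F1_high
P99	T	25.3	F1_high
Albion	C	3.90	cultivar
Camino_Real	C	4.24	cultivar
Melba	C	4.58	cultivar
Palomar	C	4.92	cultivar
Portola	C	5.26	cultivar
San_Andreas	C	5.60	cultivar
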