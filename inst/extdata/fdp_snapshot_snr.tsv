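feature	entity	role	snr
FaP1D7	07-102-41	parent	386.38
FaP1D7	Juliette	parent	513.10
FaP1D7	H	bulk	268.67
FaP1D7	L	bulk	467.90
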