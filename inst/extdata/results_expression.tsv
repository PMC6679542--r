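gene	family	nucleus	call	sparse
SCN1A	sodium	RA	higher	FALSE
SCN1A	sodium	HVC	higher	FALSE
SCN1A	sodium	LMAN	higher	FALSE
SCN1A	sodium	AreaX	higher	FALSE
SCN1A	sodium	DLM	higher	FALSE
SCN2A	sodium	RA	lower	FALSE
SCN2A	sodium	AreaX	lower	FALSE
SCN2A	sodium	LMAN	lower	FALSE
SCN2A	sodium	DLM	lower	FALSE
SCN2A	sodium	HVC	nondifferential	FALSE
SCN3A	sodium	RA	lower	FALSE
SCN3A	sodium	HVC	lower	FALSE
SCN3A	sodium	LMAN	lower	FALSE
SCN8A	sodium	RA	higher	FALSE
SCN8A	sodium	HVC	higher	FALSE
SCN5A	sodium	HVC	nondifferential	FALSE
SCN5A	sodium	RA	nondifferential	FALSE
SCN5A	sodium	AreaX	nondifferential	FALSE
SCN5A	sodium	LMAN	nondifferential	FALSE
SCN5A	sodium	nXIIts	nondifferential	FALSE
SCN9A	sodium	HVC	nondifferential	FALSE
SCN9A	sodium	RA	nondifferential	FALSE
SCN9A	sodium	AreaX	nondifferential	FALSE
SCN9A	sodium	LMAN	nondifferential	FALSE
SCN9A	sodium	nXIIts	higher	FALSE
SCN1B	sodium	HVC	higher	FALSE
SCN1B	sodium	RA	higher	FALSE
SCN1B	sodium	AreaX	higher	FALSE
SCN1B	sodium	LMAN	higher	FALSE
SCN1B	sodium	NIf	higher	FALSE
SCN1B	sodium	DLM	higher	FALSE
SCN2B	sodium	RA	nondifferential	FALSE
SCN2B	sodium	AreaX	nondifferential	FALSE
SCN2B	sodium	LMAN	nondifferential	FALSE
SCN2B	sodium	HVC	higher	FALSE
SCN3B	sodium	HVC	lower	FALSE
SCN3B	sodium	RA	lower	FALSE
SCN3B	sodium	AreaX	lower	TRUE
SCN3B	sodium	LMAN	lower	FALSE
SCN3B	sodium	nXIIts	higher	FALSE
SCN4B	sodium	RA	higher	FALSE
SCN4B	sodium	HVC	higher	FALSE
SCN4B	sodium	LMAN	higher	FALSE
ASIC1	sodium	AreaX	lower	FALSE
ASIC4	sodium	AreaX	lower	FALSE
ASIC2	sodium	nXIIts	lower	FALSE
NALCN	sodium	AreaX	lower	FALSE
CACNA1C	calcium	AreaX	higher	FALSE
CACNA1C	calcium	nXIIts	higher	FALSE
CACNA1D	calcium	RA	lower	FALSE
CACNA1D	calcium	AreaX	lower	FALSE
CACNA1D	calcium	LMAN	lower	FALSE
CACNA1E	calcium	RA	lower	FALSE
CACNA1E	calcium	LMAN	lower	FALSE
CACNA1B	calcium	HVC	higher	FALSE
CACNA1B	calcium	AreaX	higher	TRUE
CACNA1I	calcium	HVC	higher	FALSE
CACNA1I	calcium	RA	lower	FALSE
CACNA1G	calcium	RA	lower	FALSE
CACNA1H	calcium	RA	lower	FALSE
CACNA2D1	calcium	HVC	lower	FALSE
CACNA2D1	calcium	LMAN	lower	FALSE
CACNA2D2	calcium	HVC	higher	FALSE
CACNA2D2	calcium	LMAN	higher	FALSE
CACNA2D2	calcium	RA	higher	FALSE
CACNA2D2	calcium	AreaX	nondifferential	TRUE
CACNA2D3	calcium	AreaX	higher	FALSE
CACNB2	calcium	RA	lower	FALSE
CACNB2	calcium	HVC	lower	FALSE
CACNB2	calcium	LMAN	lower	FALSE
CACNB2	calcium	DLM	higher	FALSE
CACNB3	calcium	HVC	higher	FALSE
CACNB3	calcium	LMAN	higher	FALSE
CACNB4	calcium	HVC	higher	FALSE
CACNB4	calcium	AreaX	higher	FALSE
CACNG5	calcium	LMAN	lower	FALSE
CACNG5	calcium	AreaX	higher	TRUE
CACNG5	calcium	Uva	higher	FALSE
CACNG3	calcium	AreaX	lower	FALSE
CACNG3	calcium	LMAN	lower	FALSE
CACNG4	calcium	HVC	lower	FALSE
CACNG4	calcium	LMAN	lower	FALSE
CACNG4	calcium	AreaX	lower	FALSE
CACNG4	calcium	nXIIts	higher	FALSE
CACNG7	calcium	RA	higher	FALSE
CACNG7	calcium	HVC	higher	FALSE
CACNG7	calcium	AreaX	higher	FALSE
RYR2	calcium	HVC	higher	FALSE
RYR2	calcium	AreaX	higher	FALSE
RYR2	calcium	LMAN	higher	FALSE
RYR3	calcium	HVC	higher	FALSE
TPCN1	calcium	HVC	higher	FALSE
TPCN2	calcium	HVC	higher	FALSE
ITPR1	calcium	nXIIts	lower	FALSE
ANO5	chloride	HVC	higher	FALSE
ANO5	chloride	RA	higher	FALSE
CLIC4	chloride	HVC	higher	FALSE
CLIC4	chloride	RA	higher	FALSE
CLNS1A	chloride	HVC	higher	FALSE
LRRC8A	chloride	RA	lower	FALSE
LRRC8A	chloride	AreaX	lower	FALSE
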