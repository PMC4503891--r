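species_id	protein	sequence	start_residue	mods	charge	mz_printed	role	family	rt_min	peak_sd_min	response_factor
SSANYR	TnI	SSANYR	23		1	NA	analog	tni_ps	4.0	0.06	1.00
RS[p]SANYR	TnI	RSSANYR	22	phospho@3	2	467.20	phospho_mono	tni_ps	5.2	0.06	0.70
RRS[p]S[p]ANYR	TnI	RRSSANYR	21	phospho@3;phospho@4	2	585.23	phospho_bis	tni_ps	6.4	0.07	0.55
NIDALSGMEGR	TnI	NIDALSGMEGR	195		2	581.78	cterm	tni_cterm	7.6	0.06	0.90
NIDALSGM[ox]EGR	TnI	NIDALSGMEGR	195	met_sulfoxide@8	2	589.77	cterm	tni_cterm	8.6	0.06	0.90
AISEELDHALNDMTSI	Tm	AISEELDHALNDMTSI	269		2	NA	analog	tm_ps	10.0	0.08	1.10
AISEELDHALNDM[ox]TSI	Tm	AISEELDHALNDMTSI	269	met_sulfoxide@13	2	NA	analog	tm_ps	11.0	0.08	0.95
AISEELDHALNDM[ox2]TSI	Tm	AISEELDHALNDMTSI	269	met_sulfone@13	2	NA	analog	tm_ps	12.0	0.08	0.85
AISEELDHALNDMTS[p]I	Tm	AISEELDHALNDMTSI	269	phospho@15	2	919.89	phospho_mono	tm_ps	13.0	0.08	0.80
AISEELDHALNDM[ox]TS[p]I	Tm	AISEELDHALNDMTSI	269	met_sulfoxide@13;phospho@15	2	927.89	phospho_mono	tm_ps	14.0	0.08	0.75
AISEELDHALNDM[ox2]TS[p]I	Tm	AISEELDHALNDMTSI	269	met_sulfone@13;phospho@15	2	935.89	phospho_mono	tm_ps	15.0	0.08	0.70
YDVEAK	TnI	YDVEAK	1		2	362.67	reference	reference	16.0	0.05	1.20
KLQLK	TnI	KLQLK	1		1	629.43	reference	reference	2.8	0.05	0.90
ETLDLR	TnI	ETLDLR	1		1	746.40	reference	reference	16.8	0.05	1.10
NITEIADLNQK	TnI	NITEIADLNQK	1		2	629.83	reference	reference	17.6	0.06	1.30
IFDLR	TnI	IFDLR	1		2	332.19	reference	reference	18.4	0.05	0.80
HIAEDADR	Tm	HIAEDADR	1		2	463.72	reference	reference	19.2	0.05	1.00
SLEAQAEK	Tm	SLEAQAEK	1		2	438.22	reference	reference	20.0	0.05	1.15
IQLVEEELDR	Tm	IQLVEEELDR	1		2	622.33	reference	reference	20.8	0.06	1.25
LVIIESDLER	Tm	LVIIESDLER	1		2	593.83	reference	reference	21.6	0.06	0.95
SIDDLEDELYAQK	Tm	SIDDLEDELYAQK	1		2	769.86	reference	reference	22.4	0.07	1.05
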