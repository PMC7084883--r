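energy_keV	code	ssb_pct	dsb_pct	dsbp_pct	dsbpp_pct	cdsb_dsb_pct
0.30	PHITS	87.30	10.13	2.57	0.00	20.24
0.30	Geant4-DNA	93.89	4.89	1.22	0.00	20.00
0.30	KURBUC	87.19	9.18	3.28	0.35	28.31
1.00	PHITS	89.60	7.18	3.19	0.04	31.03
1.00	Geant4-DNA	94.62	4.46	0.87	0.05	17.13
1.00	KURBUC	90.65	6.51	2.55	0.29	30.38
10.0	PHITS	93.94	4.62	1.40	0.04	23.81
10.0	KURBUC	96.59	2.61	0.72	0.08	23.45
100	PHITS	94.69	3.71	1.53	0.07	30.18
100	KURBUC	96.64	2.69	0.63	0.05	20.07
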