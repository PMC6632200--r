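chain	resid	resname	na_abs	na_rel	k_abs	k_rel	sum_abs	sum_rel	site_member
A	69	PHE	28	0.05	48	0.08	76	0.13	FALSE
A	70	LYS	306	0.50	273	0.45	579	0.95	FALSE
A	71	PRO	1117	1.84	156	0.26	1273	2.10	TRUE
A	72	GLY	690	1.14	134	0.22	824	1.36	FALSE
A	73	TYR	12	0.02	0	0.00	12	0.02	FALSE
A	74	ILE	528	0.87	39	0.06	567	0.93	FALSE
A	75	ASP	819	1.35	43	0.07	862	1.42	TRUE
A	76	MET	0	0.00	0	0.00	0	0.00	FALSE
A	77	LEU	0	0.00	0	0.00	0	0.00	FALSE
A	499	TRP	74	0.12	213	0.35	287	0.47	FALSE
A	500	SER	97	0.16	322	0.53	419	0.69	FALSE
A	501	ASP	1105	1.82	307	0.51	1412	2.33	TRUE
A	502	GLU	2125	3.50	5042	8.31	7167	11.81	FALSE
A	503	GLY	0	0.00	12	0.02	12	0.02	FALSE
A	504	LYS	900	1.48	125	0.21	1025	1.69	TRUE
A	505	LEU	0	0.00	0	0.00	0	0.00	FALSE
A	506	LEU	0	0.00	1	0.00	1	0.00	FALSE
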