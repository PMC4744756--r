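peptide	pattern	percent	HB1	HB2	HB3	HB4	average	folded
ser3	oooo	7	5.87	9.67	8.06	5.00	7.15	u
ser3	oooc	3	4.14	5.56	4.40	2.30	4.10	u
ser3	cooc	22	2.29	3.77	3.82	2.18	3.01	u
ser3	cocc	47	2.40	3.70	2.17	2.13	2.60	f
ser3	ccoc	4	2.21	2.50	3.70	2.19	2.65	f
ser3	cccc	9	2.25	2.42	2.18	2.16	2.25	f
abu3	oooo	14	5.92	8.87	6.95	4.09	6.46	u
abu3	oooc	7	5.31	7.60	5.14	2.45	5.13	u
abu3	cooc	28	2.26	3.72	3.83	2.19	3.00	u
abu3	cocc	29	2.37	3.59	2.26	2.13	2.59	f
abu3	ccoc	6	2.17	2.49	3.74	2.23	2.66	f
abu3	cccc	8	2.23	2.37	2.24	2.18	2.25	f
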