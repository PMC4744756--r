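from	oooo	oooc	cooc	cocc	ccoc	cccc
oooo	94	4	0	0	0	0
oooc	9	49	23	8	3	1
cooc	0	3	72	14	7	2
cocc	0	1	6	79	1	8
ccoc	0	2	39	8	37	9
cccc	0	0	6	39	3	46
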