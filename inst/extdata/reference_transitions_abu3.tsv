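from	oooo	oooc	cooc	cocc	ccoc	cccc
oooo	87	10	0	0	0	0
oooc	21	65	8	2	1	0
cooc	0	2	75	11	8	2
cocc	0	1	11	73	1	9
ccoc	0	1	39	6	40	7
cccc	0	0	8	34	5	47
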