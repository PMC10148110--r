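gene_symbol	bsp_member	hpa	mdsec	phobius	signalp	spoctopus	secretomep_nn	secretomep_odds
YWHAB	1	0	0	0	0	0	0.82	4.6
SFN	1	1	1	0	1	0	0.71	3.8
TXNDC12	1	0	0	1	1	0	0.55	2.1
MYL6B	1	0	0	0	1	0	0.48	1.9
FN1	1	1	1	1	1	1	0.66	3.4
PSMB6	1	0	1	0	0	0	0.31	1.2
PRDX4	1	0	0	0	1	1	0.52	2.4
PEA15	1	0	0	0	0	0	0.88	5.1
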