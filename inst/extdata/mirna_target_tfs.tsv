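mirna_id	gene_symbol
miR526b	MYC
miR526b	SP3
miR526b	MECP2
miR526b	NANOG
miR526b	KLF10
miR526b	FOXP1
miR526b	ZNF148
miR526b	ETS2
miR526b	SOX4
miR526b	THRB
miR526b	ESR1
miR526b	POU5F1
miR655	MYC
miR655	SP3
miR655	MECP2
miR655	NANOG
miR655	KLF10
miR655	FOXP1
miR655	ZNF148
miR655	THRA
miR655	SRF
miR655	HNF4A
miR655	TXNDC12
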