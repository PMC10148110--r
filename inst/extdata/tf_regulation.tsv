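marker	tf_symbol	sign
MYL6B	MYC	positive
MYL6B	SP3	positive
MYL6B	MECP2	negative
TXNDC12	NANOG	negative
TXNDC12	KLF10	negative
PRDX4	FOXP1	dual
PRDX4	MYC	positive
PRDX4	NANOG	positive
PRDX4	ZNF148	negative
SFN	ETS2	negative
SFN	SOX4	negative
SFN	THRB	negative
SFN	ESR1	negative
SFN	POU5F1	negative
SFN	THRA	negative
SFN	SRF	negative
SFN	HNF4A	negative
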