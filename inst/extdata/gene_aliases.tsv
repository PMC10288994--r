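alias	canonical
MLL	KMT2A
HRX	KMT2A
AF4	AFF1
MLLT2	AFF1
AF9	MLLT3
ENL	MLLT1
AF10	MLLT10
TEL	ETV6
AML1	RUNX1
ETO	RUNX1T1
E2A	TCF3
CALM	PICALM
NKX2.5	NKX2-5
TRD@	TRD
IGH@	IGH
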