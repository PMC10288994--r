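# Leukemia-relevant fusion partner genes: events touching any of these are
# retained through the structural filters for human review.
KMT2A
AFF1
MLLT1
MLLT3
MLLT10
ELL
BCR
ABL1
ETV6
RUNX1
RUNX1T1
TCF3
PBX1
CBFB
MYH11
PML
RARA
NUP214
SET
FUS
ERG
PICALM
STIL
TAL1
P2RY8
CRLF2
TLX3
NKX2-5
LMO1
TRD
BCL11B
CBFA2T3
GLIS2
NUP98
KDM5A
MEF2D
BCL9
EP300
ZNF384
KAT6A
CREBBP
DDX3X
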