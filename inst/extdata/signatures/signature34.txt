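AGR3
AURKA
CA12
CCDC170	C6orf97
CDK12	CRKRS
CNKSR1
CWC25
DNALI1
ERBB2
ESR1
GATA3
GFRA1
GRB7
KLC4
KMO
MED1
MIEN1	C17orf37
MKI67
NANOS1
NAT1
NME3
PGAP3
PGR
PNMT
PSMD3
SIRT3
SLC15A2
SLC39A6
SOX11
STARD3
SUSD3
TBC1D9
TFF1
ZNF552
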