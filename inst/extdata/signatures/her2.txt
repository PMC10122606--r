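PNMT
CWC25
MIEN1	C17orf37
SIRT3
MED1
ERBB2
KMO
PSMD3
GRB7
CDK12	CRKRS
PGAP3
KLC4
STARD3
CNKSR1
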