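MKI67
AURKA	STK15
BIRC5
CCNB1
MYBL2
ESR1
PGR
BCL2
SCUBE2
GRB7
ERBB2
MMP11
CTSV	CTSL2
GSTM1
CD68
BAG1
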