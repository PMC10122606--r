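SUSD3
GFRA1
PGR
CCDC170	C6orf97
ESR1
NAT1
DNALI1
AGR3
CA12
TFF1
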