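TBC1D9
SUSD3
SLC39A6
GFRA1
SOX11
GATA3
SLC15A2
CCDC170	C6orf97
NANOS1
ZNF552
ESR1
NAT1
NME3
DNALI1
AGR3
CA12
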