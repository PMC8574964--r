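cell_type	gene
TU	EPCAM
TU	CLDN4
TAM	FCER1G
TAM	FCGR2A
TAT	TRAT1
TAT	THEMIS
ADI	LPL
ADI	ADIPOQ
MESO	ITLN1
MESO	HAS1
CAF	RAB3B
CAF	CDH4
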