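# Default gene-exclusion asset applied before downstream analyses.
# One symbol or glob pattern per line; '#' starts a comment line.
# Mitochondrial genes
MT-*
# Mitochondrial ribosomal proteins
MRPL*
MRPS*
# Cytosolic (40S/60S) ribosomal proteins
RPL*
RPS*
# Non-protein-coding gene families
MIR*
LINC*
# Histone genes (quantification depends on library protocol; see docs)
HIST*
H1-*
H2AC*
H2BC*
H3C*
H4C*
# Genes discordant between total-RNA and poly(A) library protocols
CCR2
CD28
CD84
MALAT1
PLCG2
RMRP
TERC
WDR74
ZNF460
CCN1
S100A14
SAA1
SAA2-SAA4
SNCG
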