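complex_name,gene_symbol
Set1C_COMPASS,CXXC1
Set1C_COMPASS,SETD1A
Set1C_COMPASS,SETD1B
Set1C_COMPASS,ASH2L
Set1C_COMPASS,DPY30
Set1C_COMPASS,RBBP5
Set1C_COMPASS,WDR5
Set1C_COMPASS,WDR82
PRC2,EZH2
PRC2,EED
PRC2,SUZ12
PRC2,RBBP4
G9a_GLP,EHMT2
G9a_GLP,EHMT1
NuA4_TIP60,KAT5
NuA4_TIP60,EP400
NuA4_TIP60,TRRAP
NuA4_TIP60,DMAP1
ATRX_DAXX,ATRX
ATRX_DAXX,DAXX
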