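subclass	label
PA_MID	LGG, other MAPK-altered
PLNTY	LGG, other MAPK-altered
PA_INF_FGFR	LGG, FGFR-altered
A_IDH_LG	LGG, IDH-altered
AG_MYB	LGG, MYB/MYBL1 fusion
LGG_MYB	LGG, MYB/MYBL1 fusion
LGG, MAPK	LGG, MAPK-altered
LGG, BRAF/MAPK	LGG, BRAF- and MAPK-altered
SEGA, To be classified	SEGA, To be classified
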