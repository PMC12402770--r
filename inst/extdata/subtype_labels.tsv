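histology_group	molecular_subtype
HGG	DMG, H3 K28
HGG	Oligodendroglioma, IDH-mutant
HGG	Oligosarcoma, IDH-mutant
HGG	PXA
HGG	DHG, H3 G35
HGG	HGG, IDH
HGG	HGG, H3 wild-type
HGG	HGG, To be classified
IHG	IHG, ALK-altered
IHG	IHG, NTRK-altered
IHG	IHG, ROS1-altered
IHG	IHG, MET-altered
IHG	IHG, To be classified
ATRT	ATRT, MYC
ATRT	ATRT, SHH
ATRT	ATRT, TYR
ATRT	ATRT, To be classified
NBL	NBL, MYCN amplified
NBL	NBL, MYCN non-amplified
NBL	NBL, To be classified
CRANIO	CRANIO, PAP
CRANIO	CRANIO, ADAM
CRANIO	CRANIO, To be classified
EPN	EPN, SP-MYCN
EPN	EPN, ST YAP1
EPN	EPN, ST ZFTA
EPN	EPN, PF A
EPN	EPN, PF B
EPN	EPN, MPE
EPN	EPN, PF SE
EPN	EPN, SP SE
EPN	EPN, SP
EPN	EPN, To be classified
LGG	LGG, other MAPK-altered
LGG	LGG, FGFR-altered
LGG	LGG, IDH-altered
LGG	LGG, MYB/MYBL1 fusion
LGG	LGG, MAPK-altered
LGG	LGG, BRAF- and MAPK-altered
LGG	SEGA, To be classified
LGG	LGG, To be classified
MB	MB, WNT
MB	MB, SHH
MB	MB, Group3
MB	MB, Group4
MB	MB, MYO
MB	MB, SHH alpha
MB	MB, SHH beta
MB	MB, SHH gamma
MB	MB, SHH delta
MB	MB, To be classified
PB	PB, MYC/FOXR2-activated
PB	PB, RB1-altered
PB	PB, Group 1
PB	PB, Group 2
PB	PB, To be classified
ETMR	ETMR, C19MC-altered
ETMR	ETMR, NOS
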