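subclass	label
PB_FOXR2	PB, MYC/FOXR2-activated
PB_RB1	PB, RB1-altered
PB_GRP1A	PB, Group 1
PB_GRP1B	PB, Group 1
PB_GRP2	PB, Group 2
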