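subclass	group
MB_G34_I	Group3
MB_G34_II	Group3
MB_G34_III	Group3
MB_G34_IV	Group3
MB_G34_V	Group4
MB_G34_VI	Group4
MB_G34_VII	Group4
MB_G34_VIII	Group4
MB_WNT	WNT
MB_MYO	MYO
MB_SHH_1	SHH
MB_SHH_2	SHH
MB_SHH_3	SHH
MB_SHH_4	SHH
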