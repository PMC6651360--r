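species,stage,accuracy_winner,pixels_winner,field_winner,chosen
MC,1,SC1,SC1,SC1,SC1
FU,1,SC4,SC4,SC4,SC4
SG,1,SC3,SC3,SC3,SC3
PA,1,SC1,SC1,SC1,SC1
MC,2,SC1_30,SC1_40,SC1_30,SC1_30
FU,2,SC4_40,SC4_40,SC4_40,SC4_40
SG,2,SC3_40,SC3_40,SC3_40,SC3_40
PA,2,SC1_30,SC1_40,SC1_40,SC1_40
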