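species,scenario,control_species_m2,control_background_m2,tp_m2,fp_m2,tn_m2,fn_m2,tp_pct,fp_pct,tn_pct,fn_pct
MC,STAGE0,14189,85667,9784,1946,83739,4387,69,14,98,31
MC,SC0,14189,85667,10840,3449,82236,3331,76,24,96,23
MC,SC1,14189,85667,9812,1774,83911,4359,69,13,98,31
MC,SC2,14189,85667,7578,878,84807,6593,53,6,99,46
MC,SC3,14189,85667,6953,694,84991,7218,49,5,99,51
MC,SC4,14189,85667,5102,460,85225,9069,36,3,99,64
MC,SC1_20,14189,85667,6123,402,85283,8048,43,3,100,57
MC,SC1_30,14189,85667,9812,1774,83911,4359,69,13,98,31
MC,SC1_40,14189,85667,9343,1737,83948,4828,66,12,98,34
FU,STAGE0,10797,89203,8134,5910,83149,2663,75,55,93,25
FU,SC0,10797,89203,6486,4406,84653,4311,60,41,95,40
FU,SC1,10797,89203,7102,5006,84053,3695,66,46,94,34
FU,SC2,10797,89203,6679,4590,84469,4118,62,43,95,38
FU,SC3,10797,89203,6287,3454,85605,4510,58,32,96,42
FU,SC4,10797,89203,6457,3126,85933,4340,60,29,96,40
FU,SC4_20,10797,89203,4684,1482,87577,6113,43,14,98,57
FU,SC4_30,10797,89203,6457,3126,85933,4340,60,29,96,40
FU,SC4_40,10797,89203,6453,3057,86002,4344,60,28,96,40
SG,STAGE0,11477,88523,7076,3398,84981,4401,62,30,96,38
SG,SC0,11477,88523,4208,10431,77948,7269,37,91,88,63
SG,SC1,11477,88523,1488,4128,84251,9989,13,36,95,87
SG,SC2,11477,88523,1916,581,87798,9561,17,5,99,83
SG,SC3,11477,88523,4061,665,87714,7416,35,6,99,65
SG,SC4,11477,88523,2575,568,87811,8902,22,5,99,78
SG,SC3_20,11477,88523,1636,211,88168,9841,14,2,100,86
SG,SC3_30,11477,88523,4061,665,87714,7416,35,6,99,65
SG,SC3_40,11477,88523,4770,638,87741,6707,42,6,99,58
PA,STAGE0,33106,66894,24417,3534,63216,8689,74,11,95,26
PA,SC0,33106,66894,18279,3409,63341,14827,55,10,95,45
PA,SC1,33106,66894,15426,1700,65050,17680,47,5,97,53
PA,SC2,33106,66894,10979,657,66093,22127,33,2,99,67
PA,SC3,33106,66894,8604,356,66394,24502,26,1,99,74
PA,SC4,33106,66894,10450,473,66277,22656,32,1,99,68
PA,SC1_20,33106,66894,3904,315,66435,29202,12,1,99,88
PA,SC1_30,33106,66894,15426,1700,65050,17680,47,5,97,53
PA,SC1_40,33106,66894,16393,1532,65218,16713,50,5,97,50
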