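line_id,specimen_no,volume_mm3,week,germ_layers,grade
201B7,1,1468,16,three_layers,3
201B7,2,1406,16,three_layers,1
201B7,3,2026,14,three_layers,3
201B7,4,648,16,three_layers,1
201B7,5,991,16,two_layers,3
201B7,6,332,16,three_layers,1
253G1,1,760,16,three_layers,1
253G1,2,139,16,two_layers,1
253G1,3,814,16,two_layers,1
253G1,4,58,16,three_layers,1
253G1,5,168,16,two_layers,1
253G1,6,1599,13,two_layers,3
409B2,3,244,16,two_layers,2
409B2,4,400,16,two_layers,3
409B2,5,43,16,three_layers,1
409B2,6,128,16,two_layers,1
454E2,1,2369,15,three_layers,3
454E2,2,2030,11,three_layers,1
454E2,3,804,16,two_layers,1
454E2,4,1592,16,two_layers,1
454E2,5,2319,15,three_layers,1
454E2,6,2021,13,three_layers,1
HiPS-RIKEN-1A,1,697,16,three_layers,3
HiPS-RIKEN-1A,2,99,16,three_layers,1
HiPS-RIKEN-1A,3,226,16,two_layers,3
HiPS-RIKEN-1A,4,273,16,three_layers,2
HiPS-RIKEN-1A,5,961,16,three_layers,1
HiPS-RIKEN-1A,6,141,16,three_layers,1
HiPS-RIKEN-2A,6,1603,9,three_layers,2
HiPS-RIKEN-12A,1,595,16,two_layers,1
HiPS-RIKEN-12A,2,85,16,three_layers,1
HiPS-RIKEN-12A,5,506,16,three_layers,3
HiPS-RIKEN-12A,6,49,16,three_layers,1
ATCC-DYR0100,1,2481,11,three_layers,3
ATCC-DYR0100,2,1172,16,three_layers,1
ATCC-DYR0100,3,2030,8,three_layers,1
ATCC-DYR0100,4,690,16,three_layers,1
ATCC-DYR0100,6,2179,14,three_layers,1
ATCC-HYR0103,2,2380,11,three_layers,1
ATCC-HYR0103,3,4218,13,three_layers,2
ATCC-HYR0103,4,2950,16,three_layers,2
ATCC-HYR0103,6,524,16,three_layers,1
mc-iPS,2,181,16,three_layers,0
mc-iPS,3,1921,15,three_layers,0
mc-iPS,5,1115,16,three_layers,3
mc-iPS,6,213,16,three_layers,1
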