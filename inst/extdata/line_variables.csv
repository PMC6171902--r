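line_id,latency_weeks,incidence_pct
201B7,6,100
253G1,4,100
409B2,5,67
454E2,4,100
HiPS-RIKEN-1A,7,100
HiPS-RIKEN-2A,6,17
HiPS-RIKEN-12A,9,67
ATCC-DYR0100,4,83
ATCC-HYR0103,9,67
mc-iPS,8,67
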