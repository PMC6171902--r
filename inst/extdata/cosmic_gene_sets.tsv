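line_id	gene
201B7	TNFRSF14
201B7	SPEN
201B7	NOTCH2
201B7	PIK3CA
201B7	TET2
201B7	FAT1
201B7	TERT
201B7	DROSHA
201B7	IL7R
201B7	APC
201B7	HLA-A
201B7	NFKBIE
201B7	KMT2C
201B7	PCM1
201B7	NCOA2
201B7	OMD
201B7	NOTCH1
201B7	KAT6B
201B7	CREB3L1
201B7	MEN1
201B7	MAML2
201B7	ATM
201B7	KCNJ5
201B7	PTPRB
201B7	SH2B3
201B7	HNF1A
201B7	NCOR2
201B7	FLT3
201B7	ERCC5
201B7	FOXA1
201B7	HIF1A
201B7	ZFHX3
201B7	TP53
201B7	BRCA1
201B7	AXIN2
201B7	SETBP1
201B7	MAP2K2
201B7	JAK3
201B7	EP300
201B7	ZRSR2
201B7	FANCB
253G1	TNFRSF14
253G1	SPEN
253G1	NOTCH2
253G1	PIK3CA
253G1	TET2
253G1	FAT1
253G1	TERT
253G1	DROSHA
253G1	IL7R
253G1	APC
253G1	HLA-A
253G1	NFKBIE
253G1	CREB3L2
253G1	KMT2C
253G1	PCM1
253G1	NCOA2
253G1	OMD
253G1	NOTCH1
253G1	KAT6B
253G1	CREB3L1
253G1	MEN1
253G1	MAML2
253G1	ATM
253G1	KCNJ5
253G1	PTPRB
253G1	SH2B3
253G1	HNF1A
253G1	NCOR2
253G1	FLT3
253G1	ERCC5
253G1	FOXA1
253G1	HIF1A
253G1	ZFHX3
253G1	TP53
253G1	BRCA1
253G1	AXIN2
253G1	SETBP1
253G1	JAK3
253G1	EP300
253G1	AR
253G1	FANCB
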