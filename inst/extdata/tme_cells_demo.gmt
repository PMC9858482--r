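CD8_T_cells	curated demo markers	CD8A	CD8B	GZMK	GZMA	CCL5	NKG7
CD4_T_cells	curated demo markers	CD4	IL7R	CD3D	CD3E	CD2	TRAC
B_cells	curated demo markers	CD19	MS4A1	CD79A	CD79B	IGHM	BLK
NK_cells	curated demo markers	NCR1	KLRD1	GNLY	KIR2DL1	KLRC1	PRF1
Macrophages	curated demo markers	CD68	CD163	MSR1	MRC1	CSF1R	LYZ
Dendritic_cells	curated demo markers	ITGAX	CD1C	CLEC9A	BATF3	FLT3	CCR7
Fibroblasts	curated demo markers	COL1A1	COL1A2	COL3A1	FAP	PDGFRA	DCN
Endothelial_cells	curated demo markers	PECAM1	VWF	CDH5	KDR	CLDN5	TEK
Adipocytes	curated demo markers	ADIPOQ	LEP	PLIN1	FABP4	CFD	LPL
Smooth_muscle	curated demo markers	ACTA2	MYH11	TAGLN	CNN1	DES	MYL9
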