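cytolytic_activity	immune-related: cytolytic effector genes	GZMA	PRF1	GZMB	GZMH	GNLY
lymphocytes	immune-related: lymphocyte markers	CD3D	CD3E	CD2	CD19	MS4A1	CD79A	IL7R	TRAC
hypoxia	vascularization-related: hypoxia response	VEGFA	SLC2A1	CA9	LDHA	PGK1	ADM	NDRG1
lymphangiogenesis	vascularization-related: lymphatic vessel genes	LYVE1	PDPN	PROX1	FLT4	VEGFC	CCL21
stromal	stromal compartment markers	COL1A1	COL1A2	COL3A1	FAP	PDGFRB	THY1	DCN	FN1
glycolysis	metabolism-related: glycolytic enzymes	HK2	PFKM	PKM	ENO1	ALDOA	GPI	TPI1
lipid_metabolism	metabolism-related: lipid handling	FASN	SCD	ACACA	CPT1A	LPL	FABP4
pentose_phosphate_pathway	metabolism-related: PPP enzymes	G6PD	PGD	TKT	TALDO1	RPIA	RPE
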