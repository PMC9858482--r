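immune_signature	synthetic stand-in immune set for tests/demos	PTPRC	CD3D	CD3E	CD2	CD52	CXCR4	LAPTM5	CD48	ITGB2	LCP2
stromal_signature	synthetic stand-in stromal set for tests/demos	COL5A1	COL6A3	THBS2	SPARC	POSTN	FBN1	MMP2	LUM	VCAN	AEBP1
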