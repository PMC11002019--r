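ipres	synthetic placeholder, innate anti-PD-1 resistance style, equal +1 weights	AXL	ROR2	WNT5A	LOXL2	TWIST2	TAGLN	FAP	VEGFA	VEGFC	CCL2	ANGPT2	ADAM12	COL4A1	SERPINE1	THBS1
chemokine	synthetic placeholder, chemokine component	CXCL9	CXCL10	CXCL11	CCL5
interferon_gamma	synthetic placeholder, interferon-gamma component	IFNG	STAT1	IDO1	HLA-DRA
t_effector	synthetic placeholder, T effector component	CD8A	GZMA	GZMB	PRF1	EOMES
t_cell_inflamed	synthetic placeholder, T-cell inflamed component	PDCD1	LAG3	CD27	CCL5	TIGIT
b_catenin	synthetic placeholder, beta-catenin component	CTNNB1	MYC	TCF7
tgf_beta	synthetic placeholder, TGF-beta component	TGFB1	TGFBR2	SMAD3
immunosuppression	synthetic placeholder, immunosuppression component	IL10	ARG1	CD163	NT5E
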