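gene	drug	interaction_type	categories
BRAF	dabrafenib	inhibitor	approved;antineoplastic
BRAF	vemurafenib	inhibitor	approved;antineoplastic
MAP2K1	trametinib	inhibitor	approved;antineoplastic
KIT	imatinib	inhibitor	approved;antineoplastic
NRAS	binimetinib	inhibitor	antineoplastic
PIK3CA	alpelisib	inhibitor	approved;antineoplastic
PTEN	everolimus	pathway	approved;antineoplastic
LAG3	relatlimab	antibody	approved;antineoplastic;immunotherapy
PDCD1	nivolumab	antibody	approved;antineoplastic;immunotherapy
PDCD1	pembrolizumab	antibody	approved;antineoplastic;immunotherapy
CTLA4	ipilimumab	antibody	approved;antineoplastic;immunotherapy
CD274	atezolizumab	antibody	approved;antineoplastic;immunotherapy
HAVCR2	cobolimab	antibody	antineoplastic;immunotherapy
TIGIT	tiragolumab	antibody	antineoplastic;immunotherapy
IDO1	epacadostat	inhibitor	antineoplastic
TGFB1	fresolimumab	antibody	immunotherapy
IL2RA	basiliximab	antibody	approved
ENTPD1	oleclumab	antibody	antineoplastic;immunotherapy
TERT	imetelstat	inhibitor	antineoplastic
CDKN2A	palbociclib	pathway	approved;antineoplastic
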