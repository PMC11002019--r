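category	gene
effector_cells	CD8A
effector_cells	CD8B
effector_cells	GZMA
effector_cells	GZMB
effector_cells	PRF1
effector_cells	IFNG
effector_cells	KLRD1
effector_cells	NKG7
suppressor_cells	FOXP3
suppressor_cells	IL10
suppressor_cells	TGFB1
suppressor_cells	CCL22
suppressor_cells	IDO1
suppressor_cells	ARG1
suppressor_cells	IL2RA
suppressor_cells	ENTPD1
checkpoints	PDCD1
checkpoints	CTLA4
checkpoints	LAG3
checkpoints	HAVCR2
checkpoints	TIGIT
checkpoints	BTLA
checkpoints	CD274
checkpoints	PDCD1LG2
MHC	HLA-A
MHC	HLA-B
MHC	HLA-C
MHC	HLA-DRA
MHC	HLA-DPB1
MHC	B2M
MHC	TAP1
MHC	TAP2
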