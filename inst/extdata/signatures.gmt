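immune	tumor-immune infiltration signature	CD8A	CD8B	CD3D	CD3E	CD3G	CD2	CD247	GZMB	GZMK	GZMH	KLRK1	KLRD1	NKG7	CCL5	CXCL9	CXCL10	CXCL11	CXCL13	IFNG	STAT1	IRF1	IDO1	PDCD1	CD274	CTLA4	LAG3	HAVCR2	TIGIT	IL2RB	IL2RG	TBX21	EOMES	PRF1	GZMA	TNF	FASLG	CD27	CD28	ICOS	TNFRSF9
CYT	cytolytic activity	GZMA	PRF1
MHC	antigen presentation machinery	HLA-A	HLA-B	HLA-C	B2M	TAP1	TAP2	NLRC5	PSMB8	PSMB9
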