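feature	category	polarity	genes
CD8_T_cells	immune_cell	anti_tumor	CD8A,CD8B,GZMK
NK_cells	immune_cell	anti_tumor	KLRD1,KLRK1,NKG7
Th1_cells	immune_cell	anti_tumor	TBX21,IFNG,STAT1
Cytotoxic_lymphocytes	immune_cell	anti_tumor	GZMA,GZMB,PRF1
Tregs	immune_cell	pro_tumor	FOXP3,IL2RA,TNFRSF18
M2_macrophages	immune_cell	pro_tumor	CD163,MRC1,ARG1
ICOS	checkpoint_gene	anti_tumor	ICOS
CD27	checkpoint_gene	anti_tumor	CD27
TNFRSF9	checkpoint_gene	anti_tumor	TNFRSF9
CD274	checkpoint_gene	pro_tumor	CD274
CTLA4	checkpoint_gene	pro_tumor	CTLA4
IFNG	cytokine	anti_tumor	IFNG
CXCL9_10	cytokine	anti_tumor	CXCL9,CXCL10
IL6	cytokine	pro_tumor	IL6
IL10	cytokine	pro_tumor	IL10
TGFB1	cytokine	pro_tumor	TGFB1
VEGFA	cytokine	pro_tumor	VEGFA
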