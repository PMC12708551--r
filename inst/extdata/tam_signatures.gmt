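C1QC	tamsig	APOE	C1QC	C1QB	C1QA	TREM2	MRC1	CD163	MERTK
SPP1_new	tamsig	PLAUR	SLC11A1	BRI3	FBP1	C15orf48
SPP1_Zhang	tamsig	SPP1	PPARG	ADM	MARCO	VEGFA	VCAN	CXCL8	ANGPTL4
CD8	tamsig	CD8A	CD8B	GZMB
Trm	tamsig	CD8A	ITGAE	ZNF683
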