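cytotoxicity	na	GZMB	GZMA	GZMH	PRF1	GNLY	NKG7	KLRG1	FASLG
pro_inflammatory	na	IFNG	TNF	IL2	IL17A	CSF2	LTA	IL21	TNFSF14
exhaustion	na	PDCD1	HAVCR2	LAG3	CTLA4	TIGIT	TOX	ENTPD1	BTLA
tissue_residency	na	ITGAE	ITGA1	ZNF683	CD69	RGS1	CXCL13	DUSP6	CRTAM
naive_memory	na	TCF7	SELL	CCR7	LEF1	IL7R	BACH2	FOXP1	KLF2
costimulatory	na	CD28	ICOS	TNFRSF9	TNFRSF4	CD27	TNFRSF18	CD40LG	SLAMF1
cytokine_receptor	na	IL2RA	IL2RB	IL12RB2	IL18R1	IL21R	IFNGR1	IL10RA	IL15RA
stress_response	na	HSPA1A	HSPA1B	DNAJB1	HSPH1	BAG3	HSPB1	HSPD1	UBC
proliferation	na	MKI67	TOP2A	CCNB1	CDK1	PCNA	TYMS	BIRC5	AURKB
apoptosis	na	BAX	BCL2L11	CASP3	CASP8	FAS	TP53	BID	APAF1
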