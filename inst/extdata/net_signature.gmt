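NET_SIGNATURE	synthetic partial reconstruction of a 23-gene neutrophil extracellular trap signature	MPO	ELANE	CTSG	PRTN3	AZU1	BPI	CAMP	DEFA1	DEFA3	DEFA4	LTF	LCP1	LYZ	CAT	S100A8	S100A9	PADI4	MMP9	CTSC	CYBB	ITGAM	FPR1	TLR4
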