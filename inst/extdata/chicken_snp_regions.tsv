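category	parent	count
UPSTREAM		18441
UTR_3_PRIME		2428
EXONIC		4005
MISSENSE	EXONIC	2070
NONSENSE	EXONIC	143
SILENT	EXONIC	1792
INTRONIC		115399
INTERGENIC		131862
UTR_5_PRIME		298
DOWNSTREAM		18899
Others		440
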