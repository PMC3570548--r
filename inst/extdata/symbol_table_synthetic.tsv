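alias	approved
MS4A1old	MS4A1
CD10	MME
CDW40	CD40
AMBIGUOUS1	GENEA
AMBIGUOUS1	GENEB
IRF4	IRF4
MUM1	IRF4
BCL6	BCL6
LAW	LRMP
SERPINA9	SERPINA9
GCET1	SERPINA9
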