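complex	mutation	foldx_ddg	mutabind2_ddg	dg_mut	dg_wt
PMCA2b	V1143F	1.98	4.24	-59.94	-61.92
PMCA3b	W1104A	15.88	3.51	-46.04	-61.92
PMCA3b	G1107D	9.29	2.39	-50.65	-61.92
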