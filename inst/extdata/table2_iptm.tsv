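group	variant	model_0	model_1	model_2	model_3	model_4	printed_lo	printed_hi
PMCA1a	WT	0.71	0.68	0.67	0.65	0.65	0.64	0.70
PMCA1b	WT	0.71	0.73	0.68	0.66	0.61	0.62	0.74
PMCA2a_2b_3b	WT	0.73	0.67	0.69	0.63	0.62	0.61	0.72
PMCA2c_2d	WT	0.59	0.53	0.54	0.55	0.53	0.52	0.58
PMCA3a	WT	0.64	0.62	0.58	0.55	0.55	0.54	0.64
PMCA4a_4c	WT	0.64	0.61	0.59	0.59	0.56	0.56	0.63
PMCA4b	WT	0.74	0.65	0.65	0.62	0.59	0.58	0.72
PMCA2b	V1143F	0.69	0.71	0.70	0.60	0.62	0.60	0.73
PMCA3b	W1104A	0.66	0.63	0.59	0.61	0.55	0.56	0.66
PMCA3b	G1107D	0.71	0.69	0.71	0.71	0.68	0.68	0.72
PMCA1a	L5R	0.69	0.67	0.66	0.67	0.62	0.63	0.69
PMCA1b	L5R	0.73	0.66	0.68	0.66	0.61	0.61	0.72
PMCA2a_2b_3b	L5R	0.80	0.70	0.68	0.68	0.68	0.64	0.77
PMCA2c_2d	L5R	0.62	0.59	0.60	0.55	0.57	0.55	0.62
PMCA3a	L5R	0.68	0.55	0.61	0.56	0.58	0.53	0.66
PMCA4a_4c	L5R	0.67	0.62	0.63	0.60	0.41	0.46	0.71
PMCA4b	L5R	0.67	0.64	0.65	0.64	0.62	0.62	0.67
PMCA1a	N6I	0.71	0.71	0.63	0.63	0.60	0.59	0.72
PMCA1b	N6I	0.68	0.65	0.63	0.65	0.61	0.61	0.68
PMCA2a_2b_3b	N6I	0.68	0.62	0.61	0.57	0.58	0.56	0.67
PMCA2c_2d	N6I	0.65	0.62	0.57	0.57	0.40	0.44	0.68
PMCA3a	N6I	0.65	0.60	0.63	0.61	0.35	0.41	0.72
PMCA4a_4c	N6I	0.57	0.61	0.55	0.58	0.53	0.53	0.61
PMCA4b	N6I	0.70	0.59	0.56	0.56	0.54	0.51	0.67
PMCA1a	I8T	0.82	0.73	0.73	0.68	0.62	0.62	0.81
PMCA1b	I8T	0.79	0.72	0.72	0.70	0.74	0.69	0.78
PMCA2a_2b_3b	I8T	0.75	0.74	0.72	0.68	0.43	0.50	0.83
PMCA2c_2d	I8T	0.63	0.63	0.63	0.63	0.58	0.59	0.65
PMCA3a	I8T	0.67	0.66	0.65	0.65	0.64	0.64	0.67
PMCA4a_4c	I8T	0.69	0.67	0.62	0.62	0.60	0.59	0.69
PMCA4b	I8T	0.70	0.63	0.61	0.58	0.62	0.57	0.68
PMCA1a	V14E/D	0.60	0.59	0.60	0.58	0.54	0.55	0.61
PMCA1b	V14E/D	0.62	0.54	0.54	0.56	0.40	0.43	0.63
PMCA2a_2b_3b	V14E/D	0.61	0.59	0.57	0.55	0.56	0.55	0.61
PMCA2c_2d	V14E/D	0.56	0.56	0.52	0.39	0.38	0.37	0.59
PMCA3a	V14E/D	0.59	0.56	0.54	0.55	0.52	0.52	0.58
PMCA4a_4c	V14E/D	0.53	0.53	0.42	0.35	0.37	0.33	0.55
PMCA4b	V14E/D	0.54	0.53	0.51	0.49	0.41	0.43	0.56
PMCA1a	F18S	0.69	0.69	0.64	0.62	0.59	0.59	0.70
PMCA1b	F18S	0.71	0.72	0.69	0.67	0.61	0.63	0.73
PMCA2a_2b_3b	F18S	0.64	0.64	0.60	0.43	0.42	0.41	0.68
PMCA2c_2d	F18S	0.68	0.60	0.59	0.63	0.60	0.57	0.67
PMCA3a	F18S	0.65	0.61	0.60	0.59	0.58	0.57	0.64
PMCA4a_4c	F18S	0.66	0.61	0.61	0.60	0.40	0.45	0.70
PMCA4b	F18S	0.58	0.60	0.57	0.47	0.45	0.45	0.62
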