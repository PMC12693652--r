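group	substitution	method	ddg
PMCA1a	L5R	foldx	-3.92
PMCA1a	N6I	foldx	-0.72
PMCA1a	I8T	foldx	-4.14
PMCA1a	V14E/D	foldx	3.42
PMCA1a	F18S	foldx	1.17
PMCA1b	L5R	foldx	-0.69
PMCA1b	N6I	foldx	-4.97
PMCA1b	I8T	foldx	5.82
PMCA1b	V14E/D	foldx	3.15
PMCA1b	F18S	foldx	5.64
PMCA2a_2b_3b	L5R	foldx	8.01
PMCA2a_2b_3b	N6I	foldx	2.91
PMCA2a_2b_3b	I8T	foldx	7.09
PMCA2a_2b_3b	V14E/D	foldx	7.29
PMCA2a_2b_3b	F18S	foldx	6.59
PMCA2c_2d	L5R	foldx	0.22
PMCA2c_2d	N6I	foldx	-8.28
PMCA2c_2d	I8T	foldx	2.21
PMCA2c_2d	V14E/D	foldx	9.19
PMCA2c_2d	F18S	foldx	4.99
PMCA3a	L5R	foldx	3.11
PMCA3a	N6I	foldx	1.15
PMCA3a	I8T	foldx	4.59
PMCA3a	V14E/D	foldx	4.99
PMCA3a	F18S	foldx	0.19
PMCA4a_4c	L5R	foldx	-2.79
PMCA4a_4c	N6I	foldx	1.72
PMCA4a_4c	I8T	foldx	3.77
PMCA4a_4c	V14E/D	foldx	12.05
PMCA4a_4c	F18S	foldx	7.90
PMCA4b	L5R	foldx	2.60
PMCA4b	N6I	foldx	8.06
PMCA4b	I8T	foldx	5.43
PMCA4b	V14E/D	foldx	16.12
PMCA4b	F18S	foldx	3.73
PMCA1a	L5R	mutabind2	1.98
PMCA1a	N6I	mutabind2	0.32
PMCA1a	I8T	mutabind2	0.32
PMCA1a	V14E/D	mutabind2	2.95
PMCA1a	F18S	mutabind2	5.04
PMCA1b	L5R	mutabind2	0.21
PMCA1b	N6I	mutabind2	0.31
PMCA1b	I8T	mutabind2	2.50
PMCA1b	V14E/D	mutabind2	3.13
PMCA1b	F18S	mutabind2	4.23
PMCA2a_2b_3b	L5R	mutabind2	1.90
PMCA2a_2b_3b	N6I	mutabind2	0.85
PMCA2a_2b_3b	I8T	mutabind2	2.53
PMCA2a_2b_3b	V14E/D	mutabind2	3.67
PMCA2a_2b_3b	F18S	mutabind2	4.20
PMCA2c_2d	L5R	mutabind2	1.72
PMCA2c_2d	N6I	mutabind2	0.72
PMCA2c_2d	I8T	mutabind2	2.57
PMCA2c_2d	V14E/D	mutabind2	3.77
PMCA2c_2d	F18S	mutabind2	4.33
PMCA3a	L5R	mutabind2	2.60
PMCA3a	N6I	mutabind2	1.56
PMCA3a	I8T	mutabind2	2.90
PMCA3a	V14E/D	mutabind2	3.35
PMCA3a	F18S	mutabind2	4.57
PMCA4a_4c	L5R	mutabind2	1.85
PMCA4a_4c	N6I	mutabind2	0.05
PMCA4a_4c	I8T	mutabind2	2.97
PMCA4a_4c	V14E/D	mutabind2	3.45
PMCA4a_4c	F18S	mutabind2	4.59
PMCA4b	L5R	mutabind2	1.92
PMCA4b	N6I	mutabind2	0.22
PMCA4b	I8T	mutabind2	2.77
PMCA4b	V14E/D	mutabind2	2.91
PMCA4b	F18S	mutabind2	4.61
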