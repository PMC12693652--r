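isoform	accession	t01	t02	t03	t04	t05	t06	t07	t08	t09	t10	t11	t12	t13	t14	t15	t16	t17	t18
PMCA1a	NP_001001323	tgg	ttt	aga	ggt	ctg	aac	aga	atc	caa	aca	cag	atg	gat	gta	gtg	aat	gct	ttc
PMCA1b	NP_001353449.1	tgg	ttt	aga	ggt	ctg	aac	aga	atc	caa	aca	cag	att	cga	gtg	gtg	aat	gca	ttt
PMCA4a	NP_001001396.1	tgg	ttc	cgg	ggc	ctg	aac	cgt	atc	cag	act	cag	atc	gac	gta	att	aac	aca	ttc
PMCA4c	NP_001352712.1	tgg	ttc	cgg	ggc	ctg	aac	cgt	atc	cag	act	cag	atc	gac	gta	att	aac	aca	ttc
PMCA2c	NP_001317540.1	tgg	ttc	cga	ggc	ctg	aat	cgg	atc	cag	aca	cag	att	gaa	gtc	gtc	aat	act	ttc
PMCA2d	NP_001350791.1	tgg	ttc	cga	ggc	ctg	aat	cgg	atc	cag	aca	cag	att	gaa	gta	gtc	aat	act	ttc
PMCA3a	NP_001375289.1	tgg	ttc	cgg	ggc	ctg	aac	cgg	att	cag	acg	cag	atg	gag	gta	gtg	agt	acc	ttc
PMCA4b	NP_001675.3	tgg	ttc	cgg	ggc	ctg	aac	cgt	atc	cag	act	cag	atc	aaa	gtg	gtc	aaa	gcg	ttc
PMCA2a	NP_001001331.1	tgg	ttc	cga	ggc	ctg	aat	cgg	atc	cag	aca	cag	atc	cgc	gtc	gtg	aag	gcg	ttc
PMCA2b	NP_001340493.1	tgg	ttc	cga	ggc	ctg	aat	cgg	atc	cag	aca	cag	atc	cgc	gtc	gtg	aag	gcg	ttc
PMCA3b	NP_001001344.1	tgg	ttc	cgg	ggc	ctg	aac	cgg	att	cag	acg	cag	atc	cgg	gtg	gtg	aaa	gcg	ttc
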