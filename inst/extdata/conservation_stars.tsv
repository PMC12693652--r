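position	stars
1	3
2	2
3	1
4	2
5	3
6	2
7	1
8	2
9	2
10	2
11	3
12	2
13	0
14	2
15	1
16	1
17	1
18	2
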