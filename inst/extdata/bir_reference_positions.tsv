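column	canonical	is_key	is_conserved15	consensus_residue
1	1	FALSE	FALSE	P
2	2	FALSE	FALSE	Q
3	3	FALSE	FALSE	H
4	4	FALSE	FALSE	A
5	5	FALSE	FALSE	H
6	6	FALSE	FALSE	N
7	7	FALSE	FALSE	Y
8	8	FALSE	FALSE	W
9	9	FALSE	FALSE	E
10	10	FALSE	FALSE	N
11	11	FALSE	FALSE	N
12	12	FALSE	FALSE	Q
13	13	FALSE	FALSE	H
14	14	FALSE	FALSE	F
15	15	FALSE	FALSE	M
16	16	FALSE	FALSE	Q
17	17	FALSE	FALSE	H
18	18	FALSE	TRUE	L
19	19	FALSE	FALSE	W
20	20	FALSE	FALSE	H
21	21	FALSE	FALSE	W
22	22	FALSE	FALSE	F
23	23	FALSE	FALSE	G
24	24	FALSE	FALSE	Q
25	25	FALSE	FALSE	Y
26	26	FALSE	TRUE	G
27	27	FALSE	FALSE	P
28	28	FALSE	FALSE	A
29	29	FALSE	FALSE	G
30	30	FALSE	FALSE	L
31	31	FALSE	FALSE	G
32	32	FALSE	FALSE	F
33	33	FALSE	FALSE	F
34	34	TRUE	TRUE	G
35	35	FALSE	FALSE	T
36	36	FALSE	FALSE	F
37	37	FALSE	FALSE	D
38	38	FALSE	FALSE	E
39	39	FALSE	FALSE	Y
40	40	FALSE	FALSE	T
41	41	FALSE	FALSE	A
42	42	FALSE	FALSE	T
43	43	FALSE	FALSE	D
44	44	FALSE	FALSE	Y
45	45	FALSE	TRUE	P
46	46	FALSE	FALSE	N
47	47	FALSE	FALSE	V
48	48	FALSE	FALSE	K
49	49	FALSE	FALSE	H
50	50	FALSE	FALSE	M
51	51	FALSE	FALSE	E
52	52	FALSE	TRUE	F
53	53	FALSE	FALSE	P
54	54	FALSE	FALSE	R
55	55	FALSE	FALSE	W
56	56	FALSE	FALSE	E
57	57	TRUE	TRUE	C
58	58	FALSE	FALSE	V
59	59	FALSE	FALSE	T
60	60	TRUE	TRUE	C
61	61	FALSE	FALSE	Q
62	62	FALSE	FALSE	N
63	63	FALSE	FALSE	T
64	64	FALSE	FALSE	W
65	65	FALSE	FALSE	I
66	66	FALSE	TRUE	W
67	67	FALSE	FALSE	P
68	68	FALSE	FALSE	A
69	69	FALSE	FALSE	T
70	70	FALSE	FALSE	V
71	71	FALSE	TRUE	D
72	72	FALSE	FALSE	E
73	73	FALSE	FALSE	C
74	74	FALSE	TRUE	P
75	75	FALSE	FALSE	D
76	76	TRUE	FALSE	A
77	77	TRUE	TRUE	H
78	78	FALSE	FALSE	Q
79	79	FALSE	FALSE	D
80	80	TRUE	FALSE	V
81	81	TRUE	FALSE	A
82	82	TRUE	FALSE	K
83	83	FALSE	FALSE	R
84	84	TRUE	TRUE	C
85	85	FALSE	FALSE	S
86	86	FALSE	FALSE	V
87	87	FALSE	FALSE	G
88	88	FALSE	FALSE	I
89	89	FALSE	TRUE	L
90	90	FALSE	FALSE	D
91	91	FALSE	FALSE	S
92	92	FALSE	FALSE	R
93	93	FALSE	TRUE	E
94	94	FALSE	FALSE	I
95	95	FALSE	FALSE	V
96	96	FALSE	FALSE	V
97	97	FALSE	TRUE	R
98	98	FALSE	FALSE	P
99	99	FALSE	FALSE	K
100	100	FALSE	FALSE	G
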