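module	n_genes	undefined_genes	unique_go_terms	total_go_terms	unique_dna_elements	total_dna_elements
1	1114	96	20	81	60	235
2	966	70	59	75	299	441
3	961	74	27	53	56	208
4	725	39	55	101	323	504
5	640	52	0	0	90	225
6	367	18	11	13	107	151
7	350	18	54	110	97	145
8	226	22	0	0	5	24
9	198	15	1	7	12	45
10	156	6	0	15	190	354
11	134	5	3	4	0	8
12	110	2	0	0	32	69
13	101	7	0	0	8	50
14	64	4	0	0	9	37
15	52	0	0	0	4	12
16	42	1	1	2	3	17
17	42	0	0	0	8	13
18	38	2	4	25	1	15
19	37	3	0	0	1	26
20	26	4	0	0	0	0
21	25	2	0	0	6	12
22	25	1	0	0	1	1
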