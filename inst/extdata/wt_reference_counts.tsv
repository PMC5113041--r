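sample_point	sim_time	obs_time	sim_count	obs_count	deviation
5	5	5	4	4	0
11	11	11	6	7	1
16	16	16	8	8	0
20	20	20	8	8	0
25	25	25	12	12	0
31	31	31	14	15	1
35	35	35	15	15	0
41	41	41	24	24	0
45	45	45	24	24	0
49	49	49	24	26	2
55	55	55	26	28	2
60	60	60	28	28	0
68	68	68	44	44	0
76	76	76	47	51	4
81	81	81	51	52	1
85	85	85	51	55	4
89	89	89	54	55	1
97	97	97	87	88	1
100	100	100	87	88	1
104	104	104	87	92	5
112	112	112	96	97	1
115	115	115	99	97	2
120	120	120	103	100	3
124	124.2464	124.2027	107	111	4
132	132.3937	132.576	154	162	8
140	140.541	140.9492	176	179	3
146	146.6515	146.5313	185	187	2
152	152.762	152.1134	188	189	1
157	157	157	190	190	0
160	160	160	191	190	1
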