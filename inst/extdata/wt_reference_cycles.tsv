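name	sim_born	sim_divided	sim_cycle	obs_born	obs_born_sd	obs_divided	obs_divided_sd	obs_cycle	obs_cycle_sd	deviation
ABala	2504	3604	1100	2508	36	3546	102	1038	108.1665	62
ABalp	2504	3503	999	2508	36	3540	102	1032	108.1665	33
ABara	2488	3498	1010	2514	36	3546	102	1032	108.1665	22
ABarp	2488	3492	1004	2514	36	3540	90	1026	96.933	22
ABpla	2522	3578	1056	2514	48	3522	96	1008	107.3313	48
ABplp	2522	3582	1060	2514	48	3552	96	1038	107.3313	22
ABpra	2501	3534	1033	2520	42	3540	96	1020	104.7855	13
ABprp	2501	3627	1126	2520	42	3582	108	1062	115.8792	64
MS	1860	2979	1119	1860	36	2928	84	1068	91.3893	51
E	1860	2948	1088	1860	36	2994	84	1134	91.3893	46
C	2094	3241	1147	2094	48	3198	108	1104	118.1863	43
P3	2094	3736	1642	2094	48	3630	132	1536	140.4564	106
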