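section	class	large_rigid	moderate_rigid	no_change	moderate_flex	large_flex	ratio
response_distance_0_8	buried	3	7	26	7	17	1.31
response_distance_0_8	moderate	1	5	30	10	12	0.93
response_distance_0_8	exposed	1	3	21	8	12	1.14
response_distance_0_8	union	5	15	77	25	41	1.12
response_distance_8_16	buried	24	38	130	28	31	0.93
response_distance_8_16	moderate	9	31	130	35	27	0.79
response_distance_8_16	exposed	9	9	81	36	18	0.89
response_distance_8_16	union	42	78	341	99	76	0.87
response_distance_16_plus	buried	25	41	155	53	23	0.92
response_distance_16_plus	moderate	23	49	174	49	29	0.86
response_distance_16_plus	exposed	32	54	200	68	46	1.00
response_distance_16_plus	union	80	144	529	170	98	0.93
response_structure	helix	95	170	553	117	45	0.77
response_structure	strand	1	4	51	30	26	1.20
response_structure	coil	31	63	343	147	144	1.12
response_structure	alpha_subdomain	115	220	693	177	69	0.84
response_structure	beta_subdomain	12	17	254	117	146	1.15
mutant_buried	dist_0_8	4	9	33	9	16	1.15
mutant_buried	dist_8_16	32	52	145	41	25	1.03
mutant_buried	dist_16_plus	28	37	153	41	25	0.86
mutant_buried	union	64	98	331	91	66	0.96
mutant_moderate	dist_0_8	0	4	23	14	17	1.52
mutant_moderate	dist_8_16	5	18	108	39	40	0.94
mutant_moderate	dist_16_plus	22	58	175	78	49	1.18
mutant_moderate	union	27	80	306	131	106	1.12
mutant_exposed	dist_0_8	1	2	21	2	8	0.62
mutant_exposed	dist_8_16	5	8	88	19	11	0.49
mutant_exposed	dist_16_plus	30	49	201	51	24	0.77
mutant_exposed	union	36	59	310	72	43	0.68
mutant_structure	helix	25	40	133	33	29	0.96
mutant_structure	strand	28	45	180	84	53	1.17
mutant_structure	coil	74	152	634	177	133	0.85
mutant_structure	alpha_subdomain	65	120	408	108	79	0.91
mutant_structure	beta_subdomain	62	117	539	186	136	0.93
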