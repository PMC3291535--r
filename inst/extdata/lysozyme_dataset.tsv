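protein	pdb_id	class	resolution_A	r_value	rmsd_A	tm_K	max_cp	n_hbonds	u_sol	v_nat
WT	1JWR	wild_type	1.4	0.18	0.7	339	15.6	244	-2.13	-0.31
WT	1LZ1	wild_type	1.4	0.18	0.6	339	17.5	240	-1.85	-0.14
WT	1LZR	wild_type	1.5	0.14	0.5	339	15.5	250	-1.86	-0.21
WT	1LZS	wild_type	1.6	0.17	0.7	339	16.3	244	-2.35	-0.37
WT	1REX	wild_type	1.5	0.19	0.8	339	15.5	234	-2.00	-0.24
WT	1REY	wild_type	1.7	0.17	0.8	339	15.1	229	-1.89	-0.12
WT	2NWD	wild_type	1.0	0.13	NA	339	15.5	238	-1.78	-0.19
K1A	1C45	mutant	1.8	0.17	0.9	337	13.1	245	-1.66	-0.18
V2A	1OUG	mutant	1.8	0.17	0.8	333	16.8	229	-1.78	-0.26
Y38F	1WQO	mutant	1.8	0.17	0.8	338	18.8	229	-1.72	-0.20
Y45F	1WQP	mutant	1.8	0.17	0.8	337	18.5	231	-1.79	-0.28
Y54F	1WQQ	mutant	1.8	0.16	0.8	337	17.3	229	-1.86	-0.29
I56T	1OUA	mutant	1.8	0.15	0.8	325	14.8	243	-1.84	-0.28
Q58G	1B7R	mutant	1.8	0.16	0.7	345	19.0	235	-1.90	-0.30
I59S	2MEG	mutant	1.8	0.15	0.8	326	14.4	239	-1.96	-0.40
Y63F	1WQR	mutant	1.8	0.17	0.7	338	18.5	239	-1.86	-0.24
P71G	1LHI	mutant	1.8	0.16	0.8	336	20.3	240	-2.10	-0.33
V74A	1OUH	mutant	1.8	0.16	1.0	337	18.8	235	-1.76	-0.23
V100A	1OUB	mutant	1.8	0.16	0.7	337	18.2	232	-1.91	-0.36
P103G	1LHJ	mutant	1.8	0.15	0.8	339	18.2	231	-1.73	-0.18
Y124F	1WQM	mutant	1.8	0.16	0.8	338	19.0	230	-1.92	-0.32
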