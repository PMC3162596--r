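rank	cluster_id	gene_symbol	gene_name	rpkm	p
1	Dr.132201	hoxc8a	Homeo box C8a	185.8	8.06E-05
2	Dr.132203	hoxc6a	Homeo box C6a	143.2	NA
3	Dr.15390	foxl1	Forkhead box L1	108.0	1.45E-03
4	Dr.89399	foxf1	Forkhead box F1	85.8	4.48E-04
5	Dr.12437	tsc22d3	TSC22 domain family, member 3	74.2	4.84E-03
6	Dr.155563	atf1	Activating transcription factor 1	63.0	4.85E-04
7	Dr.81025	foxk1	Forkhead box K1	61.5	2.41E-02
8	Dr.152531	foxq1l	Forkhead box Q, like	46.6	NA
9	Dr.139	tgif1	TGFB-induced factor homeobox 1	45.9	1.96E-02
10	Dr.80310	stat6	Signal transducer and activator of transcription 6, interleukin-4 induced	44.6	1.33E-02
11	Dr.82149	zhx3	Zinc fingers and homeoboxes 3	33.3	2.45E-02
12	Dr.20916	isl2b	Islet2b	28.0	NA
13	Dr.510	hoxc4a	Homeo box C4a	27.5	2.47E-03
14	Dr.15663	cebpg	CCAAT/enhancer binding protein (C/EBP), gamma	26.8	1.28E-02
15	Dr.32618	hoxa3a	Homeo box A3a	26.1	1.71E-03
16	Dr.91917	mnx1	Motor neuron and pancreas homeobox 1	25.9	1.63E-03
17	Dr.80606	creb3l2	cAMP responsive element binding protein 3-like 2	22.4	3.49E-03
18	Dr.8233	tbx2b	T-box 2b	22.0	1.03E-02
19	Dr.83529	hsf5	heat shock transcription factor family member 5	20.6	1.46E-03
20	Dr.114796	foxm1l	Forkhead box M1-like	17.0	7.81E-03
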