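rank	cluster_id	gene_symbol	gene_name	rpkm	p
1	Dr.20277	acta2	Actin, alpha 2, smooth muscle, aorta	75742.5	1.17E-06
2	Dr.82256	tagln	Transgelin	7296.7	2.43E-05
3	Dr.75554	sparc	Secreted acidic cysteine rich glycoprotein	3751.4	3.04E-06
4	Dr.75575	col1a2	Collagen, type I, alpha 2	2351.1	1.94E-04
5	Dr.76397	mmp2	Matrix metalloproteinase 2	2038.5	6.96E-05
6	Dr.105413	tpm1	Tropomyosin 1 (alpha)	1903.5	1.90E-05
7	Dr.76093	s100a10b	S100 calcium binding protein A10b	1821.1	8.08E-03
8	Dr.67796	icn	Ictacalcin	1584.0	4.87E-03
9	Dr.42794	ctgf	Connective tissue growth factor	1537.3	6.25E-05
10	Dr.24504	pabpc1a	Poly A binding protein, cytoplasmic 1 a	1248.1	1.14E-03
11	Dr.114623	cald1	Caldesmon 1	1226.2	5.84E-04
12	Dr.79279	lum	Lumican	1175.7	3.22E-05
13	Dr.34240	fbp2	Fructose-1,6-bisphosphatase 2	1053.9	3.96E-06
14	Dr.79127	stm	Starmaker	1023.5	9.47E-03
15	Dr.89765	zgc:103467	Myosin, light chain 9, regulatory	1014.0	1.90E-03
16	Dr.122523	dap1b	Death associated protein 1b	944.6	1.09E-02
17	Dr.76351	dcn	Decorin	839.7	2.12E-04
18	Dr.77427	b2m	Beta-2 microglobulin	798.2	1.41E-04
19	Dr.7877	mylka	Myosin, light chain kinase a	718.8	3.27E-04
20	Dr.76950	tpm4	Topomyosin alpha-4 chain	699.1	7.02E-04
21	Dr.88679	fhl2a	Four and a half LIM domains 2a	693.6	5.34E-03
22	Dr.43046	c1qtnf1	C1q and tumor necrosis factor related protein 1	682.7	1.05E-06
23	Dr.155448	bactin2	Bactin2	661.0	2.56E-04
24	Dr.86222	rergl	RERG/RAS-like	651.3	1.82E-04
25	Dr.80811	si:ch211-237l4.5	Si:ch211-237l4.5	628.6	2.24E-03
26	Dr.80402	chad	Chondroadherin	558.6	5.77E-06
27	Dr.142266	itgb1b	Integrin, beta 1b	536.1	7.00E-03
28	Dr.105090	ckba	Creatine kinase, brain a	480.9	3.89E-03
29	Dr.110680	mxra8a	Matrix-remodelling associated 8a	476.5	4.97E-05
30	Dr.150732	sdc2	Syndecan 2	465.2	7.39E-04
31	Dr.104772	LOC100332090	Thymosin, beta 4-like	453.5	1.15E-02
32	Dr.78058	myh11	Myosin, heavy polypeptide 11	448.5	2.10E-03
33	Dr.33255	tpm3	Tropomyosin 3	428.3	1.37E-02
34	Dr.81804	dkk3	Dickkopf homolog 3 (Xenopus laevis)	427.7	1.86E-04
35	Dr.76952	actn4	Actinin, alpha 4	407.0	2.55E-03
36	Dr.29018	cygb1	Cytoglobin 1	391.4	6.09E-05
37	Dr.30646	nt5c2b	5'-nucleotidase, cytosolic IIb	389.2	2.50E-06
38	Dr.560	fbln1	Fibulin 1	387.4	4.79E-05
39	Dr.15501	cyr61	cystein-rich, angiogenic inducer, 61	365.6	2.04E-03
40	Dr.75720	myl6	Myosin, light chain 6	356.6	1.38E-03
41	Dr.80990	htra1b	HtrA serine peptidase 1b	353.3	3.41E-04
42	Dr.76054	tpm4	Tropomyosin 4	350.0	1.82E-03
43	Dr.83404	csrp1a	Cysteine and glycine-rich protein 1a	349.3	3.08E-06
44	Dr.118039	tnmd	tenomodulin	341.5	3.31E-06
45	Dr.75641	cnn2	Calponin 2	339.9	3.35E-03
46	Dr.104797	cdc42	Cell division cycle 42	319.7	1.00E-02
47	Dr.26461	gpc1	Glypican 1	309.2	2.72E-03
48	Dr.76307	cav1	Caveolin 1	292.7	1.51E-02
49	Dr.94036	pthlh	Parathyroid hormone-like hormone	270.1	1.15E-04
50	Dr.11532	fbxo32	F-box protein 32	264.6	1.10E-02
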