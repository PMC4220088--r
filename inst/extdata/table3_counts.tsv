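p_printed	T	Q	k	ratio_q	ratio_t	term_id	category	term_name
7.18E-05	42	89	6	0.067	0.143	GO:0006476	BP	Protein deacetylation
1.69E-02	1274	87	18	0.207	0.014	GO:0009611	BP	Response to wounding
1.67E-04	30	72	5	0.069	0.167	GO:0042312	BP	Regulation of vasodilation
3.43E-03	28	60	4	0.067	0.143	GO:0055078	BP	Sodium ion homeostasis
1.22E-02	2	45	2	0.044	1	GO:2001295	BP	Malonyl-coenzyme A biosynthetic process
1.80E-02	32	79	4	0.051	0.125	GO:0048662	BP	Negative regulation of smooth muscle cell proliferation
4.14E-02	89	72	5	0.069	0.056	GO:0046209	BP	Nitric oxide metabolic process
4.93E-33	944	88	45	0.511	0.048	GO:0019752	BP	Carboxylic acid metabolic process
3.23E-02	41	71	4	0.056	0.098	GO:0050999	BP	Regulation of nitric oxide synthase activity
2.75E-02	83	71	5	0.07	0.06	GO:0051341	BP	Regulation of oxidoreductase activity
3.31E-02	72	85	5	0.059	0.069	GO:0006096	BP	Glycolysis
4.64E-15	7548	88	73	0.83	0.01	GO:0044444	CC	Cytoplasmic part
1.14E-02	3100	89	31	0.348	0.01	GO:0031974	CC	Membrane-enclosed lumen
5.29E-05	40	89	6	0.067	0.15	GO:0000118	CC	Histone deacetylase complex
2.54E-29	33	31	14	0.452	0.424	GO:0015020	MF	Glucuronosyltransferase activity
7.80E-04	185	72	8	0.111	0.043	GO:0005506	MF	Iron ion binding
1.94E-02	3	33	2	0.061	0.667	GO:0004769	MF	Steroid delta-isomerase activity
1.05E-14	58	79	12	0.152	0.207	GO:0033293	MF	Monocarboxylic acid binding
7.06E-09	11	89	6	0.067	0.545	GO:0031078	MF	Histone deacetylase activity (H3-K14-specific)
3.84E-02	149	72	6	0.083	0.04	GO:0020037	MF	Heme binding
4.77E-04	1195	89	20	0.225	0.017	GO:0019899	MF	Enzyme binding
3.76E-06	614	68	15	0.221	0.024	GO:0042803	MF	Protein homodimerization activity
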