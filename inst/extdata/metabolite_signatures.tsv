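metabolite	baseline_abundance	ppm	fwhm	relative_area
Creatinine	3.0	3.05	0.004	0.6
Creatinine	3.0	4.06	0.004	0.4
Glucose	8.0	3.24	0.005	0.12
Glucose	8.0	3.40	0.005	0.18
Glucose	8.0	3.46	0.005	0.15
Glucose	8.0	3.72	0.005	0.18
Glucose	8.0	3.83	0.005	0.15
Glucose	8.0	3.89	0.005	0.12
Glucose	8.0	5.23	0.004	0.10
Lactate	4.0	1.33	0.004	0.75
Lactate	4.0	4.11	0.004	0.25
Alanine	1.5	1.48	0.004	0.75
Alanine	1.5	3.78	0.004	0.25
3-Methylhistidine	1.0	7.05	0.004	0.5
3-Methylhistidine	1.0	7.67	0.004	0.5
1,3-Diaminopropane	0.8	2.00	0.005	0.5
1,3-Diaminopropane	0.8	3.12	0.005	0.5
2-Hydroxybutyric acid	1.2	0.90	0.004	0.5
2-Hydroxybutyric acid	1.2	1.70	0.005	0.3
2-Hydroxybutyric acid	1.2	4.00	0.004	0.2
2-Methoxyestrone	0.6	6.65	0.004	0.5
2-Methoxyestrone	0.6	6.95	0.004	0.5
Deoxycorticosterone	0.6	0.68	0.004	0.5
Deoxycorticosterone	0.6	5.72	0.004	0.5
Alpha ketoisovaleric acid	1.0	1.12	0.004	1.0
Iodotyrosine	0.7	6.88	0.004	0.5
Iodotyrosine	0.7	7.55	0.004	0.5
Biotin	0.8	2.20	0.005	0.6
Biotin	0.8	4.30	0.005	0.4
7-Dehydrocholesterol	0.6	0.62	0.005	0.6
7-Dehydrocholesterol	0.6	5.57	0.004	0.4
Aldosterone	0.6	5.66	0.004	0.6
Aldosterone	0.6	9.60	0.004	0.4
Dihydrobiopterin	0.7	4.20	0.005	0.5
Dihydrobiopterin	0.7	7.90	0.004	0.5
Butyric acid	1.0	0.90	0.004	0.4
Butyric acid	1.0	1.56	0.005	0.3
Butyric acid	1.0	2.16	0.005	0.3
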