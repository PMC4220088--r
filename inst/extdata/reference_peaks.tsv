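metabolite	ppm
Creatinine	3.05
Creatinine	4.06
Glucose	3.24
Glucose	3.40
Glucose	3.46
Glucose	3.72
Glucose	3.83
Glucose	3.89
Glucose	5.23
Lactate	1.33
Lactate	4.11
Alanine	1.48
Alanine	3.78
3-Methylhistidine	7.05
3-Methylhistidine	7.67
1,3-Diaminopropane	2.00
1,3-Diaminopropane	3.12
2-Hydroxybutyric acid	0.90
2-Hydroxybutyric acid	1.70
2-Hydroxybutyric acid	4.00
2-Methoxyestrone	6.65
2-Methoxyestrone	6.95
Deoxycorticosterone	0.68
Deoxycorticosterone	5.72
Alpha ketoisovaleric acid	1.12
Iodotyrosine	6.88
Iodotyrosine	7.55
Biotin	2.20
Biotin	4.30
7-Dehydrocholesterol	0.62
7-Dehydrocholesterol	5.57
Aldosterone	5.66
Aldosterone	9.60
Dihydrobiopterin	4.20
Dihydrobiopterin	7.90
Butyric acid	0.90
Butyric acid	1.56
Butyric acid	2.16
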