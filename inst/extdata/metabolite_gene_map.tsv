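metabolite	gene
3-Methylhistidine	CNDP1
3-Methylhistidine	PRMT3
1,3-Diaminopropane	AOC2
1,3-Diaminopropane	AMD1
1,3-Diaminopropane	AOC3
1,3-Diaminopropane	SMS
1,3-Diaminopropane	DHPS
1,3-Diaminopropane	ABP1
1,3-Diaminopropane	ODC1
2-Hydroxybutyric acid	DLD
2-Hydroxybutyric acid	LDHB
2-Hydroxybutyric acid	LDHAL6B
2-Hydroxybutyric acid	LDHC
2-Hydroxybutyric acid	LDHAL6A
2-Hydroxybutyric acid	TDH
2-Methoxyestrone	UGT1A1
2-Methoxyestrone	UGT2B11
2-Methoxyestrone	UGT2A3
2-Methoxyestrone	UGT2B10
2-Methoxyestrone	UGT1A5
2-Methoxyestrone	SHBG
2-Methoxyestrone	UGT1A8
2-Methoxyestrone	UGT2B15
2-Methoxyestrone	UGT1A7
2-Methoxyestrone	UGT2B7
2-Methoxyestrone	UGT2B4
2-Methoxyestrone	UGT2B28
2-Methoxyestrone	UGT1A3
2-Methoxyestrone	UGT1A6
2-Methoxyestrone	UGT2B17
2-Methoxyestrone	COMT
2-Methoxyestrone	UGT1A4
2-Methoxyestrone	UGT2A1
2-Methoxyestrone	UGT1A9
2-Methoxyestrone	UGT1A10
Deoxycorticosterone	HSD3B1
Deoxycorticosterone	P450-CYP21B
Deoxycorticosterone	CYP11B2
Deoxycorticosterone	NR3C2
Deoxycorticosterone	HSD3B2
Deoxycorticosterone	CYP11B1
Deoxycorticosterone	CYP21A2
Deoxycorticosterone	NR3C1
Alpha ketoisovaleric acid	-
Iodotyrosine	TPO
Biotin	PCCA
Biotin	SLC5A6
Biotin	PC
Biotin	PCCB
Biotin	ACACA
Biotin	MCCC1
Biotin	MCCC2
Biotin	DKFZp686B20267
Biotin	HLCS
Biotin	ACACB
Biotin	BTD
7-Dehydrocholesterol	SC5DL
7-Dehydrocholesterol	HMGCS2
7-Dehydrocholesterol	SCP2
7-Dehydrocholesterol	DHCR24
7-Dehydrocholesterol	CYP11A1
7-Dehydrocholesterol	DHCR7
Aldosterone	MLPH
Aldosterone	SGK1
Aldosterone	NR3C2
Aldosterone	NPPB
Aldosterone	CYP11B1
Aldosterone	FN1
Aldosterone	CTGF
Aldosterone	NR3C1
Aldosterone	AKR1D1
Aldosterone	ADM
Aldosterone	CYP11B2
Aldosterone	AGTR1
Aldosterone	PTGER4
Aldosterone	EGFR
Aldosterone	PRKD1
Dihydrobiopterin	TYR
Dihydrobiopterin	TH
Dihydrobiopterin	NOS3
Dihydrobiopterin	DHFR
Dihydrobiopterin	PCBD1
Dihydrobiopterin	TPH1
Dihydrobiopterin	QDPR
Dihydrobiopterin	SPR
Dihydrobiopterin	NOS1
Butyric acid	HDAC1
Butyric acid	TNF
Butyric acid	PPARG
Butyric acid	ACSM5
Butyric acid	HDAC4
Butyric acid	ACSM2A
Butyric acid	HDAC5
Butyric acid	HDAC2
Butyric acid	ACSM4
Butyric acid	ACSM1
Butyric acid	SLC16A1
Butyric acid	HDAC3
Butyric acid	ACSM2B
Butyric acid	ACSM6
Butyric acid	CASP3
Butyric acid	ACSM3
Butyric acid	HDAC9
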