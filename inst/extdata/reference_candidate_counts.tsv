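protein_name	gene_symbol	accession	control_n	control_total	control_mean	AD_n	AD_total	AD_mean	PD_n	PD_total	PD_mean
Glia-derived nexin	SERPINE2	P07093	0	0	0	8	7	2.3	3	2	1
Fibromodulin	FMOD	Q06828	0	0	0	6	4	1.5	0	0	0
Quinone oxidoreductase	NQO1	P15559	0	0	0	5	1	1	3	1	1
Cathepsin F	CTSF	Q9UBX1	1	1	1	6	5	2.3	1	1	1
Cadherin-13	CDH13	P55290	1	1	1	6	5	2	1	1	1
Phospholipase D4	PLD4	Q96BZ4	1	1	1	6	1	1	3	1	1
Inositol 1,4,5-triphosphate receptor type 1	ITPR1	Q14643	1	1	1	5	6	1.4	0	0	0
Sushi repeat-containing protein	SRPX	P78539	1	1	1	5	5	1.8	3	1	1
Sarco/endoplasmic reticulum calcium ATPase 2	ATP2A2	P16615	1	1	1	5	5	1.2	2	1	1
Oligodendrocyte-myelin glycoprotein	OMG	P23515	1	1	1	5	4	1.4	3	1	1
4F2 cell-surface antigen heavy chain	SLC3A2	P08195	1	1	1	5	4	1.2	2	1	1
WD repeat-containing protein 1	WDR1	O75083	1	1	1	5	3	1.4	2	2	1.5
Isoaspartyl peptidase	ASRGL1	Q7L266	1	1	1	5	2	1.4	2	1	1
Heterogeneous nuclear ribonucleoprotein H	HNRNPH1	P31943	1	1	1	5	2	1.2	1	1	1
Metalloproteinase inhibitor 2	TIMP2	P16035	1	1	1	5	2	1.2	1	1	1
Cerebellin-3	CBLN3	Q6UW01	1	1	1	5	2	1	0	0	0
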