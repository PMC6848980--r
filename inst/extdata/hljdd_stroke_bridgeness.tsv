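pathway_id	pathway_name	category_code	category_name	h_modules	h_pvalue	h_genes	s_module	s_pvalue	s_genes
hsa04668	TNF signaling pathway	3.2	Signal transduction	1,2	1.52E-14	ICAM1;CSF2;IL6;TNF;CCL2;PTGS2;RELA;MMP9;CXCL2;EDN1;CXCL10;MAPK1;FOS;JUN	1	0.001942	NOS1;NOS3;NOS2
hsa04066	HIF-1 signaling pathway	3.2	Signal transduction	1,2	3.85E-09	MAPK1;IL6;INS;RELA;BCL2;EDN1;VEGFA;IFNG;TLR4;STAT3	1	0.04152	PIK3CA;NOS3;NOS2
hsa04151	PI3K-Akt signaling pathway	3.2	Signal transduction	1,2	4.75E-09	IL4;IL6;IL2RA;RELA;TP53;TLR4;BCL2L1;MAPK1;INS;CHRM2;BCL2;VEGFA;FGF2;MYC;IL2	4	0.044181	IL4;ITGA2;EPO
hsa04071	Sphingolipid signaling pathway	3.2	Signal transduction	1,2	6.60E-04	MAPK1;TNF;RELA;BCL2;TP53;OPRD1	1	0.00702	TNF;GNAQ;PIK3CA;NOS3
hsa04022	cGMP-PKG signaling pathway	3.2	Signal transduction	1,2	0.002805	MAPK1;INS;ADRA2A;ADRA2C;ADRA2B;OPRD1	1	0.016942	AGTR1;GNAQ;PIK3CA;NOS3
hsa04080	Neuroactive ligand-receptor interaction	3.3	Signaling molecules and interaction	1	2.66E-05	OPRM1;PTGER3;CHRM4;C5AR1;DRD3;CHRM2;ADRA2A;ADRA2C;ADRA2B;OPRD1	1	0.012249	AGTR1;F2;TBXA2R;PLG;HTR2A
hsa04640	Hematopoietic cell lineage	5.1	Immune system	1	0.001527	IL4;CSF2;IL6;TNF;IL2RA	4	0.003017	IL4;ITGA2;EPO
hsa04915	Estrogen signaling pathway	5.2	Endocrine system	1,2	2.72E-04	OPRM1;MAPK1;FOS;JUN;MMP9;MMP2	1	0.004103	GNAQ;MMP9;PIK3CA;NOS3
hsa05200	Pathways in cancer	6.1	Cancers: Overview	1,2	2.63E-09	IL6;PTGER3;PTGS2;RELA;MMP9;TP53;BCL2L1;MMP2;STAT3;MAPK1;FOS;JUN;BCL2;VEGFA;FGF2;MYC	1	0.00833	AGTR1;GNAQ;MMP9;PIK3CA;GNB3;NOS2
hsa05142	Chagas disease (American trypanosomiasis)	6.10	Infectious diseases: Parasitic	1,2	2.93E-10	MAPK1;FOS;IL6;TNF;CCL2;JUN;RELA;IFNG;TLR4;IL10;IL2	1	0.004712	TNF;GNAQ;PIK3CA;NOS2
hsa05144	Malaria	6.10	Infectious diseases: Parasitic	1,2	3.46E-07	ICAM1;IL6;TNF;CCL2;IFNG;TLR4;IL10	4	0.048615	SELP;SELE
hsa05146	Amoebiasis	6.10	Infectious diseases: Parasitic	1,2	3.29E-05	CSF2;IL6;TNF;RELA;IFNG;TLR4;IL10	1	0.004971	TNF;GNAQ;PIK3CA;NOS2
hsa05143	African trypanosomiasis	6.10	Infectious diseases: Parasitic	1,2	3.86E-05	ICAM1;IL6;TNF;IFNG;IL10	1	1.65E-04	VCAM1;TNF;APOA1;GNAQ
hsa04931	Insulin resistance	6.7	Endocrine and metabolic diseases	1,2	0.003664	IL6;TNF;INS;RELA;STAT3	1	0.005237	SREBF1;TNF;PIK3CA;NOS3
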