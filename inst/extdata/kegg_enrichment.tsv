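pathway_id	description	fdr	members
00910	Nitrogen metabolism	5.93e-21	CA1,CA12,CA13,CA14,CA2,CA3,CA4,CA5A,CA5B,CA6,CA7,CA9
04520	Adherens junction	3.81e-12	ACP1,EGFR,ERBB2,FGFR1,FYN,INSR,MET,PTPN1,PTPN6,PTPRF,SRC,YES1
04151	PI3K-Akt signalling pathway	6.47e-09	CDK4,CDK6,CHRM1,CHRM2,CSF1R,EGFR,FGFR1,FGFR2,FGFR3,FGFR4,FLT1,FLT4,INSR,KDR,KIT,MET,NOS3
04014	Ras signalling pathway	1.22e-08	CSF1R,EGFR,FGFR1,FGFR2,FGFR3,FGFR4,FLT1,FLT4,INSR,KDR,KIT,MET,PLA2G1B,PTPN11
04015	Rap1 signalling pathway	4.72e-08	CSF1R,EGFR,FGFR1,FGFR2,FGFR3,FGFR4,FLT1,FLT4,INSR,KDR,KIT,MET,SRC
04913	Ovarian steroidogenesis	5.27e-08	ALOX5,CYP17A1,CYP19A1,CYP1B1,HSD17B1,HSD17B2,INSR,LDLR
04144	Endocytosis	1.93e-07	CSF1R,EGFR,ERBB4,FGFR2,FGFR3,FGFR4,FLT1,KDR,KIT,LDLR,MET,SRC
00590	Arachidonic acid metabolism	2.04e-07	ALOX12,ALOX12B,ALOX15,ALOX15B,ALOX5,CYP2C19,PLA2G1B,PTGES
05206	MicroRNAs in cancer	1.05e-06	ABCB1,ABCC1,CDC25A,CDC25B,CDK6,CYP1B1,EGFR,ERBB2,FGFR3,MET
00140	Steroid hormone biosynthesis	1.44e-06	CYP17A1,CYP19A1,CYP1A2,CYP1B1,HSD11B1,HSD17B1,HSD17B2
01100	Metabolic pathways	2.81e-06	AKR1A1,AKR1B1,AKR1B10,ALOX12,ALOX12B,ALOX15,ALOX15B,ALOX5,AOX1,CYP17A1,CYP19A1,CYP1A2,CYP2C19,CYP51A1,GBA,HMGCR,HSD11B1,HSD17B1,HSD17B2,NOS1,NOS2,NOS3,PLA2G1B,PTGES,XDH
05200	Pathways in cancer	4.18e-06	AR,CDK4,CDK6,CSF1R,EGFR,ERBB2,FGFR1,FGFR2,FGFR3,KIT,MET,MMP2,NOS2
05205	Proteoglycans in cancer	4.18e-06	EGFR,ERBB2,ERBB4,ESR1,FGFR1,KDR,MET,MMP2,PTPN11,PTPN6,SRC
04810	Regulation of actin cytoskeleton	2.22e-05	CHRM1,CHRM2,CHRM4,CHRM5,EGFR,FGFR1,FGFR2,FGFR3,FGFR4,SRC
04020	Calcium signalling pathway	4e-05	CHRM1,CHRM2,CHRM5,EGFR,ERBB2,ERBB4,NOS1,NOS2,NOS3
05219	Bladder cancer	7.13e-05	CDK4,EGFR,ERBB2,FGFR3,MMP2
04976	Bile secretion	8.95e-05	ABCB1,ABCC2,ABCG2,CA2,HMGCR,LDLR
04726	Serotonergic synapse	0.000115	ALOX12,ALOX12B,ALOX15,ALOX15B,ALOX5,CYP2C19,SLC6A4
00591	Linoleic acid metabolism	0.000464	ALOX15,CYP1A2,CYP2C19,PLA2G1B
04915	Estrogen signalling pathway	0.000464	EGFR,ESR1,ESR2,MMP2,NOS3,SRC
04510	Focal adhesion	0.000734	EGFR,ERBB2,FLT1,FLT4,FYN,KDR,MET,SRC
04066	HIF-1 signalling pathway	0.000751	EGFR,ERBB2,FLT1,INSR,NOS2,NOS3
04080	Neuroactive ligand-receptor interaction	0.000844	ADRA2A,ADRA2B,ADRA2C,CHRM1,CHRM2,CHRM4,CHRM5,NR3C1,PRSS1
04725	Cholinergic synapse	0.000851	ACHE,CHRM1,CHRM2,CHRM4,CHRM5,FYN
05218	Melanoma	0.000996	CDK4,CDK6,EGFR,FGFR1,MET
05204	Chemical carcinogenesis	0.0011	CYP1A2,CYP1B1,CYP2C19,HSD11B1,MGST1
02010	ABC transporters	0.00138	ABCB1,ABCC1,ABCC2,ABCG2
05215	Prostate cancer	0.00239	AR,EGFR,ERBB2,FGFR1,FGFR2
00232	Caffeine metabolism	0.00402	CYP1A2,XDH
05223	Non-small cell lung cancer	0.00402	CDK4,CDK6,EGFR,ERBB2
05212	Pancreatic cancer	0.00619	CDK4,CDK6,EGFR,ERBB2
00982	Drug metabolism - cytochrome P450	0.00678	AOX1,CYP1A2,CYP2C19,MGST1
05120	Epithelial cell signalling in Helicobacter pylori infection	0.0074	EGFR,MET,PTPN11,SRC
00980	Metabolism of xenobiotics by cytochrome P450	0.00805	CYP1A2,CYP1B1,HSD11B1,MGST1
04917	Prolactin signaling pathway	0.00873	CYP17A1,ESR1,ESR2,SRC
00040	Pentose and glucuronate interconversions	0.01	AKR1A1,AKR1B1,AKR1B10
04010	MAPK signalling pathway	0.01	CDC25B,EGFR,FGFR1,FGFR2,FGFR3,FGFR4,MAPT
04060	Cytokine-cytokine receptor interaction	0.0119	CSF1R,EGFR,FLT1,FLT4,KDR,KIT,MET
00380	Tryptophan metabolism	0.0151	AOX1,CYP1A2,CYP1B1
04012	ErbB signalling pathway	0.0151	EGFR,ERBB2,ERBB4,SRC
04022	cGMP-PKG signalling pathway	0.0256	ADRA2A,ADRA2B,ADRA2C,INSR,NOS3
05202	Transcriptional mis-regulation in cancer	0.03	CSF1R,FLT1,MET,MMP3,MPO
00561	Glycolipid metabolism	0.0349	AKR1A1,AKR1B1,AKR1B10
00330	Arginine and proline metabolism	0.0397	NOS1,NOS2,NOS3
04370	VEGF signalling pathway	0.0418	KDR,NOS3,SRC
04964	Proximal tubule bicarbonate reclamation	0.0418	CA2,CA4
05214	Glioma	0.0449	CDK4,CDK6,EGFR
04110	Cell cycle	0.0483	CDC25A,CDC25B,CDK4,CDK6
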