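pathway	database	hierarchy	gene	gnomad_rare_cases	gnomad_rare_controls	gnomad_vrare_cases	gnomad_vrare_controls	exac_rare_cases	exac_rare_controls	exac_vrare_cases	exac_vrare_controls	note
Antigen activates B Cell Receptor (BCR) leading to generation of second messengers	Reactome	Adaptive Immune System	BLK	1	33	1	33	NA	NA	NA	NA
Antigen activates B Cell Receptor (BCR) leading to generation of second messengers	Reactome	Adaptive Immune System	IGLV3-25	1	27	1	27	NA	NA	NA	NA
Antigen activates B Cell Receptor (BCR) leading to generation of second messengers	Reactome	Adaptive Immune System	IGLV7-43	1	48	1	48	NA	NA	NA	NA
Antigen activates B Cell Receptor (BCR) leading to generation of second messengers	Reactome	Adaptive Immune System	SYK	1	2	1	2	NA	NA	NA	NA
DAP12 signaling	Reactome	Innate Immune System	GRAP2	1	13	1	13	NA	NA	NA	NA
DAP12 signaling	Reactome	Innate Immune System	SYK	1	2	1	2	NA	NA	NA	NA
FCERI mediated Ca+2 mobilization	Reactome	Innate Immune System	GRAP2	1	13	1	13	NA	NA	NA	NA
FCERI mediated Ca+2 mobilization	Reactome	Innate Immune System	IGLV3-25	1	27	1	27	NA	NA	NA	NA
FCERI mediated Ca+2 mobilization	Reactome	Innate Immune System	IGLV7-43	1	48	1	48	NA	NA	NA	NA
FCERI mediated Ca+2 mobilization	Reactome	Innate Immune System	SYK	1	2	1	2	NA	NA	NA	NA
FCERI mediated MAPK activation	Reactome	Innate Immune System	GRAP2	1	13	1	13	NA	NA	NA	NA
FCERI mediated MAPK activation	Reactome	Innate Immune System	IGLV3-25	1	27	1	27	NA	NA	NA	NA
FCERI mediated MAPK activation	Reactome	Innate Immune System	IGLV7-43	1	48	1	48	NA	NA	NA	NA
FCERI mediated MAPK activation	Reactome	Innate Immune System	SYK	1	2	1	2	NA	NA	NA	NA
FCGR activation	Reactome	Innate Immune System	SYK	1	2	1	2	NA	NA	NA	NA
FCGR activation	Reactome	Innate Immune System	IGLV3-25	1	27	1	27	NA	NA	NA	NA
FCGR activation	Reactome	Innate Immune System	IGLV7-43	1	48	1	48	NA	NA	NA	NA
Regulation of actin dynamics for phagocytic cup formation	Reactome	Innate Immune System	SYK	1	2	1	2	NA	NA	NA	NA
Regulation of actin dynamics for phagocytic cup formation	Reactome	Innate Immune System	IGLV3-25	1	27	1	27	NA	NA	NA	NA
Regulation of actin dynamics for phagocytic cup formation	Reactome	Innate Immune System	IGLV7-43	1	48	1	48	NA	NA	NA	NA
Role of LAT2/NTAL/LAB on calcium mobilization	Reactome	Innate Immune System	SYK	1	2	1	2	NA	NA	NA	NA
Role of LAT2/NTAL/LAB on calcium mobilization	Reactome	Innate Immune System	IGLV3-25	1	27	1	27	NA	NA	NA	NA
Role of LAT2/NTAL/LAB on calcium mobilization	Reactome	Innate Immune System	IGLV7-43	1	48	1	48	NA	NA	NA	NA
Role of phospholipids in phagocytosis	Reactome	Innate Immune System	SYK	1	2	1	2	NA	NA	NA	NA
Role of phospholipids in phagocytosis	Reactome	Innate Immune System	IGLV3-25	1	27	1	27	NA	NA	NA	NA
Role of phospholipids in phagocytosis	Reactome	Innate Immune System	IGLV7-43	1	48	1	48	NA	NA	NA	NA
FCGR3A-mediated IL10 synthesis	Reactome	Leishmania infection	SYK	1	2	1	2	NA	NA	NA	NA
FCGR3A-mediated IL10 synthesis	Reactome	Leishmania infection	IGLV3-25	1	27	1	27	NA	NA	NA	NA
FCGR3A-mediated IL10 synthesis	Reactome	Leishmania infection	IGLV7-43	1	48	1	48	NA	NA	NA	NA
FCGR3A-mediated phagocytosis	Reactome	Leishmania infection	SYK	1	2	1	2	NA	NA	NA	NA
FCGR3A-mediated phagocytosis	Reactome	Leishmania infection	IGLV3-25	1	27	1	27	NA	NA	NA	NA
FCGR3A-mediated phagocytosis	Reactome	Leishmania infection	IGLV7-43	1	48	1	48	NA	NA	NA	NA
Post-translational protein phosphorylation	Reactome	Metabolism of proteins	AMBN	NA	NA	1	53	NA	NA	1	24
Post-translational protein phosphorylation	Reactome	Metabolism of proteins	CP	NA	NA	1	34	NA	NA	1	22
Post-translational protein phosphorylation	Reactome	Metabolism of proteins	PENK	NA	NA	1	29	NA	NA	1	25
Regulation of Insulin-like Growth Factor (IGF) transport and uptake by Insulin-like Growth Factor Binding Proteins (IGFBPs)	Reactome	Metabolism of proteins	AMBN	NA	NA	1	53	NA	NA	1	24
Regulation of Insulin-like Growth Factor (IGF) transport and uptake by Insulin-like Growth Factor Binding Proteins (IGFBPs)	Reactome	Metabolism of proteins	CP	NA	NA	1	34	NA	NA	1	22
Regulation of Insulin-like Growth Factor (IGF) transport and uptake by Insulin-like Growth Factor Binding Proteins (IGFBPs)	Reactome	Metabolism of proteins	PENK	NA	NA	1	29	NA	NA	1	25
Drug metabolism cytochrome p450	KEGG	NA	AOX1	NA	NA	1	85	NA	NA	NA	NA
Drug metabolism cytochrome p450	KEGG	NA	CYP2B6	NA	NA	1	45	NA	NA	NA	NA
Drug metabolism cytochrome p450	KEGG	NA	FMO3	NA	NA	1	113	NA	NA	NA	NA
Drug metabolism cytochrome p450	KEGG	NA	GSTK1	NA	NA	1	67	NA	NA	NA	NA
Olfactory transduction	KEGG	NA	OR1N2	1	41	1	41	1	58	1	58
Olfactory transduction	KEGG	NA	OR2AG2	1	61	1	61	1	39	1	39
Olfactory transduction	KEGG	NA	OR52B2	1	54	1	54	1	29	1	29
Olfactory transduction	KEGG	NA	OR52M1	1	488	1	119	1	287	1	54
Olfactory transduction	KEGG	NA	OR6V1	2	245	1	22	1	52	1	52
Olfactory transduction	KEGG	NA	OR6C6	1	52	NA	NA	1	51	1	51
Olfactory transduction	KEGG	NA	OR6C4	1	138	1	52	1	32	NA	NA
Olfactory transduction	KEGG	NA	GUCA1C	2	937	NA	NA	2	425	NA	NA
Olfactory transduction	KEGG	NA	OR10C1	2	664	NA	NA	2	388	NA	NA
Olfactory transduction	KEGG	NA	OR51E1	1	164	NA	NA	1	109	NA	NA
Olfactory transduction	KEGG	NA	OR51G1	1	1458	NA	NA	1	835	NA	NA
Olfactory transduction	KEGG	NA	OR6C70	1	470	NA	NA	1	259	NA	NA
Peroxisome	KEGG	NA	CROT	1	317	1	317	1	160	1	159
Peroxisome	KEGG	NA	GSTK1	1	67	1	67	1	51	1	51
Peroxisome	KEGG	NA	EHHADH	2	119	1	119	2	58	2	58	printed_inconsistent_gnomad_vrare_cases
Peroxisome	KEGG	NA	PEX7	2	106	1	106	2	47	2	47	printed_inconsistent_gnomad_vrare_cases
Purine metabolism	KEGG	NA	AMPD1	NA	NA	1	52	NA	NA	1	25
Purine metabolism	KEGG	NA	ATIC	NA	NA	1	73	NA	NA	1	47
Purine metabolism	KEGG	NA	NUDT2	NA	NA	1	34	NA	NA	1	14
Purine metabolism	KEGG	NA	PDE11A	NA	NA	1	115	NA	NA	1	65
Retinol metabolism	KEGG	NA	CYP1A1	NA	NA	1	62	NA	NA	NA	NA
Retinol metabolism	KEGG	NA	CYP2B6	NA	NA	1	45	NA	NA	NA	NA
Retinol metabolism	KEGG	NA	DGAT2	NA	NA	1	116	NA	NA	NA	NA
Retinol metabolism	KEGG	NA	RPE65	NA	NA	1	52	NA	NA	NA	NA
Tryptophan metabolism	KEGG	NA	AOX1	NA	NA	1	85	NA	NA	NA	NA
Tryptophan metabolism	KEGG	NA	CYP1A1	NA	NA	1	62	NA	NA	NA	NA
Tryptophan metabolism	KEGG	NA	EHHADH	NA	NA	2	119	NA	NA	NA	NA
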