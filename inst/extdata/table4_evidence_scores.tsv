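signal_rsid	closest_gene	gene	base_score	ub_column	published_total
rs61816761	FLG	FLG	2	0	2
rs61816761	FLG	TUFT1	0	1	2
rs61816761	FLG	SELENBP1	0	1	2
rs61816761	FLG	C1orf68	0	1	2
rs7523907	CD247	CD247	7	0	7
rs7523907	CD247	BRP44	0	1	2
rs7523907	CD247	CREG1	0	1	2
rs12479210	IL1RL1	IL1RL1	11	1	13
rs12479210	IL1RL1	IL1R1	0	1	2
rs12479210	IL1RL1	IL18R1	6	0	6
rs34290285	D2HGDH	D2HGDH	11	1	13
rs34290285	D2HGDH	PDCD1	3	0	3
rs34290285	D2HGDH	GAL3ST2	1	0	1
rs34290285	D2HGDH	KIF1A	1	1	3
rs560026225	KIAA1109	KIAA1109	4	0	4
rs1837253	TSLP	TSLP	2	0	2
rs1837253	TSLP	WDR36	1	0	1
rs1438673	WDR36	WDR36	3	0	3
rs1438673	WDR36	CAMK4	1	0	1
rs1438673	WDR36	TMEM232	0	1	2
rs1438673	WDR36	TSLP	1	1	3
rs1438673	WDR36	STMN1	0	1	2
rs3749833	C5orf56	SLC22A5	8	0	8
rs3749833	C5orf56	SLC22A4	2	0	2
rs3749833	C5orf56	P4HA2	2	0	2
rs3749833	C5orf56	C5orf56	1	0	1
rs3749833	C5orf56	IRF1	3	0	3
rs3749833	C5orf56	LOC553103	0	1	2
rs3749833	C5orf56	SEPT8	0	1	2
rs3749833	C5orf56	ANKRD43	0	1	2
rs1986009	RAD50	SLC22A5	3	0	3
rs1986009	RAD50	SLC22A4	3	0	3
rs1986009	RAD50	ACSL6	0	1	2
rs1986009	RAD50	IL13	0	1	2
rs1986009	RAD50	IL4	0	1	2
rs9273410	HLA-DQB1	HLA-DQB1	2	3	8
rs9273410	HLA-DQB1	HLA-DQB2	2	3	8
rs9273410	HLA-DQB1	HLA-DQA1	2	0	2
rs9273410	HLA-DQB1	HLA-DQA2	2	0	2
rs9273410	HLA-DQB1	ATF6B	1	0	1
rs776111176	HLA-DQA1	HLA-DQA1	6	2	8
rs776111176	HLA-DQA1	HLA-DQA2	6	0	6
rs776111176	HLA-DQA1	HLA-DQB1	6	6	12
rs776111176	HLA-DQA1	HLA-DQB2	6	0	6
rs776111176	HLA-DQA1	HLA-DRB3	0	2	2
rs776111176	HLA-DQA1	HLA-DOB	4	0	4
rs776111176	HLA-DQA1	AGER	0	2	2
rs776111176	HLA-DQA1	LY6G6E	0	2	2
rs776111176	HLA-DQA1	PFDN6	0	2	2
rs776111176	HLA-DQA1	NEU1	0	2	2
rs776111176	HLA-DQA1	DOM3Z	0	2	2
rs776111176	HLA-DQA1	LY6G6D	0	2	2
rs776111176	HLA-DQA1	COL11A2	0	2	2
rs367983479	BACH2	BACH2	3	0	3
rs367983479	BACH2	ANKRD6	0	1	2
rs367983479	BACH2	MAP3K7	0	1	2
rs367983479	BACH2	GABRR2	0	1	2
rs71266076	MIR5708	ZBTB10	1	0	1
rs144829310	IL33	IL33	2	2	6
rs144829310	IL33	ERMP1	1	0	1
rs144829310	IL33	TPD52L3	0	1	2
rs10905284	GATA3	GATA3	2	0	2
rs11603634	MUC5AC	MUC5AC	2	2	6
rs11603634	MUC5AC	TNNT3	0	1	2
rs7936312	C11orf30	LRRC32	4	0	4
rs7936312	C11orf30	BRCA2	1	0	1
rs7305461	RPS26	RPS26	4	0	4
rs7305461	RPS26	SUOX	4	0	4
rs7305461	RPS26	RAB5B	2	0	2
rs7305461	RPS26	ERBB3	2	0	2
rs7305461	RPS26	ESYT1	1	0	1
rs7305461	RPS26	GDF11	1	0	1
rs7305461	RPS26	RNF41	1	0	1
rs703816	STAT6	STAT6	5	0	5
rs703816	STAT6	NEMP1	1	0	1
rs703816	STAT6	RBMS2	1	0	1
rs703816	STAT6	SPRYD4	1	0	1
rs703816	STAT6	EEF1AKMT3	1	0	1
rs703816	STAT6	ZBTB39	0	1	2
rs703816	STAT6	CDK4	0	1	2
rs703816	STAT6	ESYT1	0	1	2
rs10519068	RORA	RORA	4	0	4
rs10519068	RORA	ICE2	0	1	2
rs10519068	RORA	ANXA2	0	1	2
rs10519068	RORA	FOXB1	0	1	2
rs72743461	SMAD3	SMAD3	4	0	4
rs72743461	SMAD3	AAGAB	3	0	3
rs72743461	SMAD3	C15orf61	0	1	2
rs72743461	SMAD3	BPGM	0	1	2
rs72743461	SMAD3	MAP2K1	0	1	2
rs7203459	CLEC16A	CLEC16A	2	1	4
rs7203459	CLEC16A	TEKT5	0	1	2
rs7203459	CLEC16A	PRM1	0	1	2
rs7203459	CLEC16A	DEXI	3	0	3
rs2941522	IKZF3	ORMDL3	4	0	4
rs2941522	IKZF3	GSDMB	5	0	5
rs2941522	IKZF3	GSDMA	2	0	2
rs2941522	IKZF3	PGAP3	3	0	3
rs2941522	IKZF3	MSL1	1	1	3
rs2941522	IKZF3	IKZF3	2	0	2
rs2941522	IKZF3	ARL5C	0	1	2
rs112502960	ZNF652	ZNF652	3	0	3
rs112502960	ZNF652	GNGT2	3	0	3
rs112502960	ZNF652	PHOSPHO1	2	0	2
rs112502960	ZNF652	TMEM92	0	1	2
rs112502960	ZNF652	HOXB4	0	1	2
rs112502960	ZNF652	NCRNA00253	0	1	2
rs61840192	LOC101928272	GATA3	4	0	4
rs61840192	LOC101928272	GATA3-AS1	2	0	2
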