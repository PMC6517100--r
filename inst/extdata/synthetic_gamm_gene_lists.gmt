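microglia	synthetic	P2RY12	TMEM119	CX3CR1	GPR34	OLFML3	SALL1	SLC2A5	SIGLEC11	SELPLG	CSF1R	AIF1	HEXB	SPARC	GPR84	P2RY13	BIN1	CTSS	CST3	ITGAM	TREM2	TMEM175	SYK	BLNK	LAG3	ADORA3	ENTPD1	TAL1	IRF8	SPI1	MEF2C	MAFB	CSF3R	IL21R	LTC4S	SCAMP5	CMTM4	LHFPL2	SERPINE2	SLCO2B1	P2RX7	MICSYN001	MICSYN002	MICSYN003	MICSYN004	MICSYN005	MICSYN006	MICSYN007	MICSYN008	MICSYN009	MICSYN010	MICSYN011	MICSYN012	MICSYN013	MICSYN014	MICSYN015	MICSYN016	MICSYN017	MICSYN018	MICSYN019	MICSYN020	MICSYN021	MICSYN022	MICSYN023	MICSYN024	MICSYN025	MICSYN026	MICSYN027	MICSYN028	MICSYN029	MICSYN030	MICSYN031	MICSYN032	MICSYN033	MICSYN034	MICSYN035	MICSYN036	MICSYN037	MICSYN038	MICSYN039	MICSYN040	MICSYN041	MICSYN042	MICSYN043	MICSYN044	MICSYN045	MICSYN046	MICSYN047	MICSYN048	MICSYN049	MICSYN050	MICSYN051	MICSYN052	MICSYN053	MICSYN054	MICSYN055	MICSYN056	MICSYN057	MICSYN058	MICSYN059	MICSYN060	MICSYN061	MICSYN062	MICSYN063	MICSYN064	MICSYN065	MICSYN066	MICSYN067	MICSYN068	MICSYN069	MICSYN070	MICSYN071	MICSYN072	MICSYN073	MICSYN074	MICSYN075	MICSYN076	MICSYN077	MICSYN078	MICSYN079	MICSYN080	MICSYN081	MICSYN082	MICSYN083	MICSYN084	MICSYN085	MICSYN086	MICSYN087	MICSYN088	MICSYN089	MICSYN090	MICSYN091	MICSYN092	MICSYN093	MICSYN094	MICSYN095	MICSYN096	MICSYN097	MICSYN098	MICSYN099	MICSYN100	MICSYN101	MICSYN102	MICSYN103	MICSYN104	MICSYN105	MICSYN106	MICSYN107	MICSYN108	MICSYN109	MICSYN110
macrophage	synthetic	FCER1G	TYROBP	C1QA	C1QB	C1QC	CD74	MRC1	LYZ	CD14	FCGR1A	FCGR3A	S100A8	S100A9	S100A11	VCAN	FN1	CCR2	ITGA4	TGFBI	F13A1	CD44	AHR	EMILIN2	HP	SELL	CRIP1	NCF1	TGM2	CD36	MSR1	APOE	APOC1	FTL	FCN1	PLAUR	CLEC12A	LILRB4	SERPINA1	SLC11A1	CD163L1	MACSYN001	MACSYN002	MACSYN003	MACSYN004	MACSYN005	MACSYN006	MACSYN007	MACSYN008	MACSYN009	MACSYN010	MACSYN011	MACSYN012	MACSYN013	MACSYN014	MACSYN015	MACSYN016	MACSYN017	MACSYN018	MACSYN019	MACSYN020	MACSYN021	MACSYN022	MACSYN023	MACSYN024	MACSYN025	MACSYN026	MACSYN027	MACSYN028	MACSYN029	MACSYN030	MACSYN031	MACSYN032	MACSYN033	MACSYN034	MACSYN035	MACSYN036	MACSYN037	MACSYN038	MACSYN039	MACSYN040	MACSYN041	MACSYN042	MACSYN043	MACSYN044	MACSYN045	MACSYN046	MACSYN047	MACSYN048	MACSYN049	MACSYN050	MACSYN051	MACSYN052	MACSYN053	MACSYN054	MACSYN055	MACSYN056	MACSYN057	MACSYN058	MACSYN059	MACSYN060	MACSYN061	MACSYN062	MACSYN063	MACSYN064	MACSYN065	MACSYN066	MACSYN067	MACSYN068	MACSYN069	MACSYN070	MACSYN071	MACSYN072	MACSYN073	MACSYN074	MACSYN075	MACSYN076	MACSYN077	MACSYN078	MACSYN079	MACSYN080	MACSYN081	MACSYN082	MACSYN083	MACSYN084	MACSYN085	MACSYN086	MACSYN087	MACSYN088	MACSYN089	MACSYN090	MACSYN091	MACSYN092	MACSYN093	MACSYN094	MACSYN095	MACSYN096	MACSYN097	MACSYN098	MACSYN099	MACSYN100	MACSYN101	MACSYN102	MACSYN103	MACSYN104	MACSYN105	MACSYN106	MACSYN107	MACSYN108	MACSYN109	MACSYN110
pro_inflammatory	synthetic	TNF	IL1B	IL1A	IL6	IL12A	IL12B	IL18	CXCL9	CXCL10	CXCL11	NOS2	CD80	CD86	CCL2	CCL3	CCL4	CCL5	IL23A	NFKB1	RELA	STAT1	IRF1	IRF5	TLR2	TLR4	CD40	HLA-DRA	HLA-DRB1	SOCS3	PTGS2	CASP1	NLRP3	IFIT1	IFIT3	ISG15	GBP1	GBP2	SERPING1	EDN1	IL15	PROSYN001	PROSYN002	PROSYN003	PROSYN004	PROSYN005	PROSYN006	PROSYN007	PROSYN008	PROSYN009	PROSYN010	PROSYN011	PROSYN012	PROSYN013	PROSYN014	PROSYN015	PROSYN016	PROSYN017	PROSYN018	PROSYN019	PROSYN020	PROSYN021	PROSYN022	PROSYN023	PROSYN024	PROSYN025	PROSYN026	PROSYN027	PROSYN028	PROSYN029	PROSYN030	PROSYN031	PROSYN032	PROSYN033	PROSYN034	PROSYN035	PROSYN036	PROSYN037	PROSYN038	PROSYN039	PROSYN040	PROSYN041	PROSYN042	PROSYN043	PROSYN044	PROSYN045	PROSYN046	PROSYN047	PROSYN048	PROSYN049	PROSYN050	PROSYN051	PROSYN052	PROSYN053	PROSYN054	PROSYN055	PROSYN056	PROSYN057	PROSYN058	PROSYN059	PROSYN060	PROSYN061	PROSYN062	PROSYN063	PROSYN064	PROSYN065	PROSYN066	PROSYN067	PROSYN068	PROSYN069	PROSYN070	PROSYN071	PROSYN072	PROSYN073	PROSYN074	PROSYN075	PROSYN076	PROSYN077	PROSYN078	PROSYN079	PROSYN080	PROSYN081	PROSYN082	PROSYN083	PROSYN084	PROSYN085	PROSYN086	PROSYN087	PROSYN088	PROSYN089	PROSYN090	PROSYN091	PROSYN092	PROSYN093	PROSYN094	PROSYN095	PROSYN096	PROSYN097	PROSYN098	PROSYN099	PROSYN100	PROSYN101	PROSYN102	PROSYN103	PROSYN104	PROSYN105	PROSYN106	PROSYN107	PROSYN108	PROSYN109	PROSYN110
anti_inflammatory	synthetic	IL10	TGFB1	TGFB2	TGFB3	CD163	MRC1	ARG1	CHI3L1	CHI3L2	CCL22	CCL17	IL4R	STAT6	MSR1	LGALS1	LGALS3	VEGFA	MMP9	MMP14	TREM2	GPNMB	IL1RN	SOCS1	KLF4	PPARG	RETNLB	CLEC7A	CD33	LILRB2	SIRPA	CD200R1	MERTK	GAS6	AXL	TNFSF13	IL13RA1	STAB1	F13A1	FOLR2	SEPP1	ANTSYN001	ANTSYN002	ANTSYN003	ANTSYN004	ANTSYN005	ANTSYN006	ANTSYN007	ANTSYN008	ANTSYN009	ANTSYN010	ANTSYN011	ANTSYN012	ANTSYN013	ANTSYN014	ANTSYN015	ANTSYN016	ANTSYN017	ANTSYN018	ANTSYN019	ANTSYN020	ANTSYN021	ANTSYN022	ANTSYN023	ANTSYN024	ANTSYN025	ANTSYN026	ANTSYN027	ANTSYN028	ANTSYN029	ANTSYN030	ANTSYN031	ANTSYN032	ANTSYN033	ANTSYN034	ANTSYN035	ANTSYN036	ANTSYN037	ANTSYN038	ANTSYN039	ANTSYN040	ANTSYN041	ANTSYN042	ANTSYN043	ANTSYN044	ANTSYN045	ANTSYN046	ANTSYN047	ANTSYN048	ANTSYN049	ANTSYN050	ANTSYN051	ANTSYN052	ANTSYN053	ANTSYN054	ANTSYN055	ANTSYN056	ANTSYN057	ANTSYN058	ANTSYN059	ANTSYN060	ANTSYN061	ANTSYN062	ANTSYN063	ANTSYN064	ANTSYN065	ANTSYN066	ANTSYN067	ANTSYN068	ANTSYN069	ANTSYN070	ANTSYN071	ANTSYN072	ANTSYN073	ANTSYN074	ANTSYN075	ANTSYN076	ANTSYN077	ANTSYN078	ANTSYN079	ANTSYN080	ANTSYN081	ANTSYN082	ANTSYN083	ANTSYN084	ANTSYN085	ANTSYN086	ANTSYN087	ANTSYN088	ANTSYN089	ANTSYN090	ANTSYN091	ANTSYN092	ANTSYN093	ANTSYN094	ANTSYN095	ANTSYN096	ANTSYN097	ANTSYN098	ANTSYN099	ANTSYN100	ANTSYN101	ANTSYN102	ANTSYN103	ANTSYN104	ANTSYN105	ANTSYN106	ANTSYN107	ANTSYN108	ANTSYN109	ANTSYN110
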