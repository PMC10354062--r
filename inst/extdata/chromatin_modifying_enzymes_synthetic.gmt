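Chromatin_Modifying_Enzymes_synthetic	Synthetic stand-in for a 274-gene chromatin-modifying-enzyme set: real recurrent chromatin gene symbols plus synthetic placeholders	EP400	KAT6A	KMT2C	KMT2D	NSD1	PHF21A	CHD7	EZH2	ATAD2B	TRRAP	SMAD4	DNMT3A	HLTF	KDM4B	KMT2E	BRPF3	IPO9	NSD2	CHRSYN001	CHRSYN002	CHRSYN003	CHRSYN004	CHRSYN005	CHRSYN006	CHRSYN007	CHRSYN008	CHRSYN009	CHRSYN010	CHRSYN011	CHRSYN012	CHRSYN013	CHRSYN014	CHRSYN015	CHRSYN016	CHRSYN017	CHRSYN018	CHRSYN019	CHRSYN020	CHRSYN021	CHRSYN022	CHRSYN023	CHRSYN024	CHRSYN025	CHRSYN026	CHRSYN027	CHRSYN028	CHRSYN029	CHRSYN030	CHRSYN031	CHRSYN032	CHRSYN033	CHRSYN034	CHRSYN035	CHRSYN036	CHRSYN037	CHRSYN038	CHRSYN039	CHRSYN040	CHRSYN041	CHRSYN042	CHRSYN043	CHRSYN044	CHRSYN045	CHRSYN046	CHRSYN047	CHRSYN048	CHRSYN049	CHRSYN050	CHRSYN051	CHRSYN052	CHRSYN053	CHRSYN054	CHRSYN055	CHRSYN056	CHRSYN057	CHRSYN058	CHRSYN059	CHRSYN060	CHRSYN061	CHRSYN062	CHRSYN063	CHRSYN064	CHRSYN065	CHRSYN066	CHRSYN067	CHRSYN068	CHRSYN069	CHRSYN070	CHRSYN071	CHRSYN072	CHRSYN073	CHRSYN074	CHRSYN075	CHRSYN076	CHRSYN077	CHRSYN078	CHRSYN079	CHRSYN080	CHRSYN081	CHRSYN082	CHRSYN083	CHRSYN084	CHRSYN085	CHRSYN086	CHRSYN087	CHRSYN088	CHRSYN089	CHRSYN090	CHRSYN091	CHRSYN092	CHRSYN093	CHRSYN094	CHRSYN095	CHRSYN096	CHRSYN097	CHRSYN098	CHRSYN099	CHRSYN100	CHRSYN101	CHRSYN102	CHRSYN103	CHRSYN104	CHRSYN105	CHRSYN106	CHRSYN107	CHRSYN108	CHRSYN109	CHRSYN110	CHRSYN111	CHRSYN112	CHRSYN113	CHRSYN114	CHRSYN115	CHRSYN116	CHRSYN117	CHRSYN118	CHRSYN119	CHRSYN120	CHRSYN121	CHRSYN122	CHRSYN123	CHRSYN124	CHRSYN125	CHRSYN126	CHRSYN127	CHRSYN128	CHRSYN129	CHRSYN130	CHRSYN131	CHRSYN132	CHRSYN133	CHRSYN134	CHRSYN135	CHRSYN136	CHRSYN137	CHRSYN138	CHRSYN139	CHRSYN140	CHRSYN141	CHRSYN142	CHRSYN143	CHRSYN144	CHRSYN145	CHRSYN146	CHRSYN147	CHRSYN148	CHRSYN149	CHRSYN150	CHRSYN151	CHRSYN152	CHRSYN153	CHRSYN154	CHRSYN155	CHRSYN156	CHRSYN157	CHRSYN158	CHRSYN159	CHRSYN160	CHRSYN161	CHRSYN162	CHRSYN163	CHRSYN164	CHRSYN165	CHRSYN166	CHRSYN167	CHRSYN168	CHRSYN169	CHRSYN170	CHRSYN171	CHRSYN172	CHRSYN173	CHRSYN174	CHRSYN175	CHRSYN176	CHRSYN177	CHRSYN178	CHRSYN179	CHRSYN180	CHRSYN181	CHRSYN182	CHRSYN183	CHRSYN184	CHRSYN185	CHRSYN186	CHRSYN187	CHRSYN188	CHRSYN189	CHRSYN190	CHRSYN191	CHRSYN192	CHRSYN193	CHRSYN194	CHRSYN195	CHRSYN196	CHRSYN197	CHRSYN198	CHRSYN199	CHRSYN200	CHRSYN201	CHRSYN202	CHRSYN203	CHRSYN204	CHRSYN205	CHRSYN206	CHRSYN207	CHRSYN208	CHRSYN209	CHRSYN210	CHRSYN211	CHRSYN212	CHRSYN213	CHRSYN214	CHRSYN215	CHRSYN216	CHRSYN217	CHRSYN218	CHRSYN219	CHRSYN220	CHRSYN221	CHRSYN222	CHRSYN223	CHRSYN224	CHRSYN225	CHRSYN226	CHRSYN227	CHRSYN228	CHRSYN229	CHRSYN230	CHRSYN231	CHRSYN232	CHRSYN233	CHRSYN234	CHRSYN235	CHRSYN236	CHRSYN237	CHRSYN238	CHRSYN239	CHRSYN240	CHRSYN241	CHRSYN242	CHRSYN243	CHRSYN244	CHRSYN245	CHRSYN246	CHRSYN247	CHRSYN248	CHRSYN249	CHRSYN250	CHRSYN251	CHRSYN252	CHRSYN253	CHRSYN254	CHRSYN255	CHRSYN256
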