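region_id	name	abbreviation	hemisphere	compartment	network_tag
1	Precentral_L	PreCG.L	left	cerebral	
2	Precentral_R	PreCG.R	right	cerebral	
3	Frontal_Sup_L	SFGdor.L	left	cerebral	
4	Frontal_Sup_R	SFGdor.R	right	cerebral	
5	Frontal_Sup_Orb_L	ORBsup.L	left	cerebral	
6	Frontal_Sup_Orb_R	ORBsup.R	right	cerebral	
7	Frontal_Mid_L	MFG.L	left	cerebral	
8	Frontal_Mid_R	MFG.R	right	cerebral	
9	Frontal_Mid_Orb_L	ORBmid.L	left	cerebral	
10	Frontal_Mid_Orb_R	ORBmid.R	right	cerebral	
11	Frontal_Inf_Oper_L	IFGoperc.L	left	cerebral	
12	Frontal_Inf_Oper_R	IFGoperc.R	right	cerebral	
13	Frontal_Inf_Tri_L	IFGtriang.L	left	cerebral	
14	Frontal_Inf_Tri_R	IFGtriang.R	right	cerebral	
15	Frontal_Inf_Orb_L	ORBinf.L	left	cerebral	
16	Frontal_Inf_Orb_R	ORBinf.R	right	cerebral	
17	Rolandic_Oper_L	ROL.L	left	cerebral	
18	Rolandic_Oper_R	ROL.R	right	cerebral	
19	Supp_Motor_Area_L	SMA.L	left	cerebral	
20	Supp_Motor_Area_R	SMA.R	right	cerebral	
21	Olfactory_L	OLF.L	left	cerebral	
22	Olfactory_R	OLF.R	right	cerebral	
23	Frontal_Sup_Medial_L	SFGmed.L	left	cerebral	DMN
24	Frontal_Sup_Medial_R	SFGmed.R	right	cerebral	DMN
25	Frontal_Med_Orb_L	ORBsupmed.L	left	cerebral	DMN
26	Frontal_Med_Orb_R	ORBsupmed.R	right	cerebral	DMN
27	Rectus_L	REC.L	left	cerebral	
28	Rectus_R	REC.R	right	cerebral	
29	Insula_L	INS.L	left	cerebral	
30	Insula_R	INS.R	right	cerebral	
31	Cingulum_Ant_L	ACG.L	left	cerebral	
32	Cingulum_Ant_R	ACG.R	right	cerebral	
33	Cingulum_Mid_L	MCG.L	left	cerebral	
34	Cingulum_Mid_R	MCG.R	right	cerebral	
35	Cingulum_Post_L	PCG.L	left	cerebral	DMN
36	Cingulum_Post_R	PCG.R	right	cerebral	DMN
37	Hippocampus_L	HIP.L	left	cerebral	
38	Hippocampus_R	HIP.R	right	cerebral	
39	ParaHippocampal_L	PHG.L	left	cerebral	
40	ParaHippocampal_R	PHG.R	right	cerebral	
41	Amygdala_L	AMYG.L	left	cerebral	
42	Amygdala_R	AMYG.R	right	cerebral	
43	Calcarine_L	CAL.L	left	cerebral	
44	Calcarine_R	CAL.R	right	cerebral	
45	Cuneus_L	CUN.L	left	cerebral	
46	Cuneus_R	CUN.R	right	cerebral	
47	Lingual_L	LING.L	left	cerebral	
48	Lingual_R	LING.R	right	cerebral	
49	Occipital_Sup_L	SOG.L	left	cerebral	
50	Occipital_Sup_R	SOG.R	right	cerebral	
51	Occipital_Mid_L	MOG.L	left	cerebral	
52	Occipital_Mid_R	MOG.R	right	cerebral	
53	Occipital_Inf_L	IOG.L	left	cerebral	
54	Occipital_Inf_R	IOG.R	right	cerebral	
55	Fusiform_L	FFG.L	left	cerebral	
56	Fusiform_R	FFG.R	right	cerebral	
57	Postcentral_L	PoCG.L	left	cerebral	
58	Postcentral_R	PoCG.R	right	cerebral	
59	Parietal_Sup_L	SPG.L	left	cerebral	
60	Parietal_Sup_R	SPG.R	right	cerebral	
61	Parietal_Inf_L	IPL.L	left	cerebral	
62	Parietal_Inf_R	IPL.R	right	cerebral	
63	SupraMarginal_L	SMG.L	left	cerebral	
64	SupraMarginal_R	SMG.R	right	cerebral	
65	Angular_L	ANG.L	left	cerebral	DMN
66	Angular_R	ANG.R	right	cerebral	DMN
67	Precuneus_L	PCUN.L	left	cerebral	DMN
68	Precuneus_R	PCUN.R	right	cerebral	DMN
69	Paracentral_Lobule_L	PCL.L	left	cerebral	
70	Paracentral_Lobule_R	PCL.R	right	cerebral	
71	Caudate_L	CAU.L	left	cerebral	
72	Caudate_R	CAU.R	right	cerebral	
73	Putamen_L	PUT.L	left	cerebral	
74	Putamen_R	PUT.R	right	cerebral	
75	Pallidum_L	PAL.L	left	cerebral	
76	Pallidum_R	PAL.R	right	cerebral	
77	Thalamus_L	THA.L	left	cerebral	
78	Thalamus_R	THA.R	right	cerebral	
79	Heschl_L	HES.L	left	cerebral	
80	Heschl_R	HES.R	right	cerebral	
81	Temporal_Sup_L	STG.L	left	cerebral	
82	Temporal_Sup_R	STG.R	right	cerebral	
83	Temporal_Pole_Sup_L	TPOsup.L	left	cerebral	
84	Temporal_Pole_Sup_R	TPOsup.R	right	cerebral	
85	Temporal_Mid_L	MTG.L	left	cerebral	DMN
86	Temporal_Mid_R	MTG.R	right	cerebral	DMN
87	Temporal_Pole_Mid_L	TPOmid.L	left	cerebral	
88	Temporal_Pole_Mid_R	TPOmid.R	right	cerebral	
89	Temporal_Inf_L	ITG.L	left	cerebral	
90	Temporal_Inf_R	ITG.R	right	cerebral	
91	Cerebelum_Crus1_L	CERCRU1.L	left	cerebellar	
92	Cerebelum_Crus1_R	CERCRU1.R	right	cerebellar	
93	Cerebelum_Crus2_L	CERCRU2.L	left	cerebellar	
94	Cerebelum_Crus2_R	CERCRU2.R	right	cerebellar	
95	Cerebelum_3_L	CER3.L	left	cerebellar	
96	Cerebelum_3_R	CER3.R	right	cerebellar	
97	Cerebelum_4_5_L	CER4_5.L	left	cerebellar	
98	Cerebelum_4_5_R	CER4_5.R	right	cerebellar	
99	Cerebelum_6_L	CER6.L	left	cerebellar	
100	Cerebelum_6_R	CER6.R	right	cerebellar	
101	Cerebelum_7b_L	CER7b.L	left	cerebellar	
102	Cerebelum_7b_R	CER7b.R	right	cerebellar	
103	Cerebelum_8_L	CER8.L	left	cerebellar	
104	Cerebelum_8_R	CER8.R	right	cerebellar	
105	Cerebelum_9_L	CER9.L	left	cerebellar	
106	Cerebelum_9_R	CER9.R	right	cerebellar	
107	Cerebelum_10_L	CER10.L	left	cerebellar	
108	Cerebelum_10_R	CER10.R	right	cerebellar	
109	Vermis_1_2	VER1_2	midline	cerebellar	
110	Vermis_3	VER3	midline	cerebellar	
111	Vermis_4_5	VER4_5	midline	cerebellar	
112	Vermis_6	VER6	midline	cerebellar	
113	Vermis_7	VER7	midline	cerebellar	
114	Vermis_8	VER8	midline	cerebellar	
115	Vermis_9	VER9	midline	cerebellar	
116	Vermis_10	VER10	midline	cerebellar	
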