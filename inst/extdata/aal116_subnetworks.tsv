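aal_number	region_name	subnetwork
1	Precentral_L	unassigned
2	Precentral_R	SH
3	Frontal_Sup_L	DMN
4	Frontal_Sup_R	DMN
5	Frontal_Sup_Orb_L	DMN
6	Frontal_Sup_Orb_R	unassigned
7	Frontal_Mid_L	unassigned
8	Frontal_Mid_R	FTC
9	Frontal_Mid_Orb_L	FTC
10	Frontal_Mid_Orb_R	unassigned
11	Frontal_Inf_Oper_L	unassigned
12	Frontal_Inf_Oper_R	FTC
13	Frontal_Inf_Tri_L	unassigned
14	Frontal_Inf_Tri_R	FTC
15	Frontal_Inf_Orb_L	DMN
16	Frontal_Inf_Orb_R	DMN
17	Rolandic_Oper_L	CTC
18	Rolandic_Oper_R	AN
19	Supp_Motor_Area_L	unassigned
20	Supp_Motor_Area_R	SH
21	Olfactory_L	unassigned
22	Olfactory_R	DMN
23	Frontal_Sup_Medial_L	DMN
24	Frontal_Sup_Medial_R	DMN
25	Frontal_Mid_Orb_L	DMN
26	Frontal_Mid_Orb_R	DMN
27	Rectus_L	unassigned
28	Rectus_R	unassigned
29	Insula_L	SN
30	Insula_R	SN
31	Cingulum_Ant_L	unassigned
32	Cingulum_Ant_R	unassigned
33	Cingulum_Mid_L	DMN
34	Cingulum_Mid_R	DMN
35	Cingulum_Post_L	DMN
36	Cingulum_Post_R	DMN
37	Hippocampus_L	DMN
38	Hippocampus_R	DMN
39	ParaHippocampal_L	DMN
40	ParaHippocampal_R	unassigned
41	Amygdala_L	SBN
42	Amygdala_R	SBN
43	Calcarine_L	VN
44	Calcarine_R	unassigned
45	Cuneus_L	unassigned
46	Cuneus_R	unassigned
47	Lingual_L	DMN
48	Lingual_R	VN
49	Occipital_Sup_L	VN
50	Occipital_Sup_R	VN
51	Occipital_Mid_L	VN
52	Occipital_Mid_R	DMN
53	Occipital_Inf_L	VN
54	Occipital_Inf_R	VN
55	Fusiform_L	DMN
56	Fusiform_R	unassigned
57	Postcentral_L	SH
58	Postcentral_R	SH
59	Parietal_Sup_L	DAN
60	Parietal_Sup_R	DAN
61	Parietal_Inf_L	DMN
62	Parietal_Inf_R	DMN
63	SupraMarginal_L	AN
64	SupraMarginal_R	AN
65	Angular_L	DMN
66	Angular_R	DMN
67	Precuneus_L	DMN
68	Precuneus_R	DMN
69	Paracentral_Lobule_L	unassigned
70	Paracentral_Lobule_R	SH
71	Caudate_L	unassigned
72	Caudate_R	SBN
73	Putamen_L	SBN
74	Putamen_R	SBN
75	Pallidum_L	unassigned
76	Pallidum_R	SBN
77	Thalamus_L	SBN
78	Thalamus_R	SBN
79	Heschl_L	AN
80	Heschl_R	AN
81	Temporal_Sup_L	unassigned
82	Temporal_Sup_R	AN
83	Temporal_Pole_Sup_L	CTC
84	Temporal_Pole_Sup_R	DMN
85	Temporal_Mid_L	DMN
86	Temporal_Mid_R	DMN
87	Temporal_Pole_Mid_L	DMN
88	Temporal_Pole_Mid_R	DMN
89	Temporal_Inf_L	unassigned
90	Temporal_Inf_R	FTC
91	Cerebelum_Crus1_L	unassigned
92	Cerebelum_Crus1_R	unassigned
93	Cerebelum_Crus2_L	unassigned
94	Cerebelum_Crus2_R	unassigned
95	Cerebelum_3_L	unassigned
96	Cerebelum_3_R	unassigned
97	Cerebelum_4_5_L	unassigned
98	Cerebelum_4_5_R	unassigned
99	Cerebelum_6_L	unassigned
100	Cerebelum_6_R	unassigned
101	Cerebelum_7b_L	unassigned
102	Cerebelum_7b_R	unassigned
103	Cerebelum_8_L	unassigned
104	Cerebelum_8_R	unassigned
105	Cerebelum_9_L	unassigned
106	Cerebelum_9_R	unassigned
107	Cerebelum_10_L	unassigned
108	Cerebelum_10_R	unassigned
109	Vermis_1_2	unassigned
110	Vermis_3	unassigned
111	Vermis_4_5	unassigned
112	Vermis_6	unassigned
113	Vermis_7	unassigned
114	Vermis_8	unassigned
115	Vermis_9	unassigned
116	Vermis_10	unassigned
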