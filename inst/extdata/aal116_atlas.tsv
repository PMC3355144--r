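region_id	name	hemisphere	homolog_id	cortical
0	Precentral_L	left	1	TRUE
1	Precentral_R	right	1	TRUE
2	Frontal_Sup_L	left	2	TRUE
3	Frontal_Sup_R	right	2	TRUE
4	Frontal_Sup_Orb_L	left	3	TRUE
5	Frontal_Sup_Orb_R	right	3	TRUE
6	Frontal_Mid_L	left	4	TRUE
7	Frontal_Mid_R	right	4	TRUE
8	Frontal_Mid_Orb_L	left	5	TRUE
9	Frontal_Mid_Orb_R	right	5	TRUE
10	Frontal_Inf_Oper_L	left	6	TRUE
11	Frontal_Inf_Oper_R	right	6	TRUE
12	Frontal_Inf_Tri_L	left	7	TRUE
13	Frontal_Inf_Tri_R	right	7	TRUE
14	Frontal_Inf_Orb_L	left	8	TRUE
15	Frontal_Inf_Orb_R	right	8	TRUE
16	Rolandic_Oper_L	left	9	TRUE
17	Rolandic_Oper_R	right	9	TRUE
18	Supp_Motor_Area_L	left	10	TRUE
19	Supp_Motor_Area_R	right	10	TRUE
20	Olfactory_L	left	11	TRUE
21	Olfactory_R	right	11	TRUE
22	Frontal_Sup_Medial_L	left	12	TRUE
23	Frontal_Sup_Medial_R	right	12	TRUE
24	Frontal_Med_Orb_L	left	13	TRUE
25	Frontal_Med_Orb_R	right	13	TRUE
26	Rectus_L	left	14	TRUE
27	Rectus_R	right	14	TRUE
28	Insula_L	left	15	TRUE
29	Insula_R	right	15	TRUE
30	Cingulum_Ant_L	left	16	TRUE
31	Cingulum_Ant_R	right	16	TRUE
32	Cingulum_Mid_L	left	17	TRUE
33	Cingulum_Mid_R	right	17	TRUE
34	Cingulum_Post_L	left	18	TRUE
35	Cingulum_Post_R	right	18	TRUE
36	Hippocampus_L	left	19	TRUE
37	Hippocampus_R	right	19	TRUE
38	ParaHippocampal_L	left	20	TRUE
39	ParaHippocampal_R	right	20	TRUE
40	Amygdala_L	left	21	TRUE
41	Amygdala_R	right	21	TRUE
42	Calcarine_L	left	22	TRUE
43	Calcarine_R	right	22	TRUE
44	Cuneus_L	left	23	TRUE
45	Cuneus_R	right	23	TRUE
46	Lingual_L	left	24	TRUE
47	Lingual_R	right	24	TRUE
48	Occipital_Sup_L	left	25	TRUE
49	Occipital_Sup_R	right	25	TRUE
50	Occipital_Mid_L	left	26	TRUE
51	Occipital_Mid_R	right	26	TRUE
52	Occipital_Inf_L	left	27	TRUE
53	Occipital_Inf_R	right	27	TRUE
54	Fusiform_L	left	28	TRUE
55	Fusiform_R	right	28	TRUE
56	Postcentral_L	left	29	TRUE
57	Postcentral_R	right	29	TRUE
58	Parietal_Sup_L	left	30	TRUE
59	Parietal_Sup_R	right	30	TRUE
60	Parietal_Inf_L	left	31	TRUE
61	Parietal_Inf_R	right	31	TRUE
62	SupraMarginal_L	left	32	TRUE
63	SupraMarginal_R	right	32	TRUE
64	Angular_L	left	33	TRUE
65	Angular_R	right	33	TRUE
66	Precuneus_L	left	34	TRUE
67	Precuneus_R	right	34	TRUE
68	Paracentral_Lobule_L	left	35	TRUE
69	Paracentral_Lobule_R	right	35	TRUE
70	Caudate_L	left	36	TRUE
71	Caudate_R	right	36	TRUE
72	Putamen_L	left	37	TRUE
73	Putamen_R	right	37	TRUE
74	Pallidum_L	left	38	TRUE
75	Pallidum_R	right	38	TRUE
76	Thalamus_L	left	39	TRUE
77	Thalamus_R	right	39	TRUE
78	Heschl_L	left	40	TRUE
79	Heschl_R	right	40	TRUE
80	Temporal_Sup_L	left	41	TRUE
81	Temporal_Sup_R	right	41	TRUE
82	Temporal_Pole_Sup_L	left	42	TRUE
83	Temporal_Pole_Sup_R	right	42	TRUE
84	Temporal_Mid_L	left	43	TRUE
85	Temporal_Mid_R	right	43	TRUE
86	Temporal_Pole_Mid_L	left	44	TRUE
87	Temporal_Pole_Mid_R	right	44	TRUE
88	Temporal_Inf_L	left	45	TRUE
89	Temporal_Inf_R	right	45	TRUE
90	Cerebelum_Crus1_L	left	NA	FALSE
91	Cerebelum_Crus1_R	right	NA	FALSE
92	Cerebelum_Crus2_L	left	NA	FALSE
93	Cerebelum_Crus2_R	right	NA	FALSE
94	Cerebelum_3_L	left	NA	FALSE
95	Cerebelum_3_R	right	NA	FALSE
96	Cerebelum_4_5_L	left	NA	FALSE
97	Cerebelum_4_5_R	right	NA	FALSE
98	Cerebelum_6_L	left	NA	FALSE
99	Cerebelum_6_R	right	NA	FALSE
100	Cerebelum_7b_L	left	NA	FALSE
101	Cerebelum_7b_R	right	NA	FALSE
102	Cerebelum_8_L	left	NA	FALSE
103	Cerebelum_8_R	right	NA	FALSE
104	Cerebelum_9_L	left	NA	FALSE
105	Cerebelum_9_R	right	NA	FALSE
106	Cerebelum_10_L	left	NA	FALSE
107	Cerebelum_10_R	right	NA	FALSE
108	Vermis_1_2	midline	NA	FALSE
109	Vermis_3	midline	NA	FALSE
110	Vermis_4_5	midline	NA	FALSE
111	Vermis_6	midline	NA	FALSE
112	Vermis_7	midline	NA	FALSE
113	Vermis_8	midline	NA	FALSE
114	Vermis_9	midline	NA	FALSE
115	Vermis_10	midline	NA	FALSE
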