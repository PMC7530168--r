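# Reconstructed 90-region neonatal AAL parcellation table.
# Region ordering is reconstructed to satisfy the published lobe index ranges
# (frontal 1-28 & 69-70, occipital 43-54, central 55-60, parietal 61-68,
# temporal 37-42 & 71-90) and the published abbreviation set; slots not pinned
# down by either are filled with the remaining standard AAL-90 region pairs by
# convention. Indices 29-36 are not assigned a lobe by the source listing and
# carry the tag 'unlisted'. Left/right homologues occupy odd/even indices.
index	name	abbreviation	lobe
1	Precentral gyrus left	PreCG-L	frontal
2	Precentral gyrus right	PreCG-R	frontal
3	Superior frontal gyrus (dorsal) left	SFGdor-L	frontal
4	Superior frontal gyrus (dorsal) right	SFGdor-R	frontal
5	Orbitofrontal cortex (superior) left	ORBsup-L	frontal
6	Orbitofrontal cortex (superior) right	ORBsup-R	frontal
7	Middle frontal gyrus left	MFG-L	frontal
8	Middle frontal gyrus right	MFG-R	frontal
9	Orbitofrontal cortex (middle) left	ORBmid-L	frontal
10	Orbitofrontal cortex (middle) right	ORBmid-R	frontal
11	Inferior frontal gyrus (opercular) left	IFGoperc-L	frontal
12	Inferior frontal gyrus (opercular) right	IFGoperc-R	frontal
13	Inferior frontal gyrus (triangular) left	IFGtriang-L	frontal
14	Inferior frontal gyrus (triangular) right	IFGtriang-R	frontal
15	Orbitofrontal cortex (inferior) left	ORBinf-L	frontal
16	Orbitofrontal cortex (inferior) right	ORBinf-R	frontal
17	Rolandic operculum left	ROL-L	frontal
18	Rolandic operculum right	ROL-R	frontal
19	Supplementary motor area left	SMA-L	frontal
20	Supplementary motor area right	SMA-R	frontal
21	Olfactory cortex left	OLF-L	frontal
22	Olfactory cortex right	OLF-R	frontal
23	Superior frontal gyrus (medial) left	SFGmed-L	frontal
24	Superior frontal gyrus (medial) right	SFGmed-R	frontal
25	Orbitofrontal cortex (medial) left	ORBmed-L	frontal
26	Orbitofrontal cortex (medial) right	ORBmed-R	frontal
27	Gyrus rectus left	REC-L	frontal
28	Gyrus rectus right	REC-R	frontal
29	Insula left	INS-L	unlisted
30	Insula right	INS-R	unlisted
31	Anterior cingulate gyrus left	ACG-L	unlisted
32	Anterior cingulate gyrus right	ACG-R	unlisted
33	Middle cingulate gyrus left	DCG-L	unlisted
34	Middle cingulate gyrus right	DCG-R	unlisted
35	Posterior cingulate gyrus left	PCG-L	unlisted
36	Posterior cingulate gyrus right	PCG-R	unlisted
37	Hippocampus left	HIP-L	temporal
38	Hippocampus right	HIP-R	temporal
39	Parahippocampal gyrus left	PHG-L	temporal
40	Parahippocampal gyrus right	PHG-R	temporal
41	Amygdala left	AMYG-L	temporal
42	Amygdala right	AMYG-R	temporal
43	Calcarine cortex left	CAL-L	occipital
44	Calcarine cortex right	CAL-R	occipital
45	Cuneus left	CUN-L	occipital
46	Cuneus right	CUN-R	occipital
47	Lingual gyrus left	LING-L	occipital
48	Lingual gyrus right	LING-R	occipital
49	Superior occipital gyrus left	SOG-L	occipital
50	Superior occipital gyrus right	SOG-R	occipital
51	Middle occipital gyrus left	MOG-L	occipital
52	Middle occipital gyrus right	MOG-R	occipital
53	Inferior occipital gyrus left	IOG-L	occipital
54	Inferior occipital gyrus right	IOG-R	occipital
55	Caudate nucleus left	CAU-L	central
56	Caudate nucleus right	CAU-R	central
57	Putamen left	PUT-L	central
58	Putamen right	PUT-R	central
59	Thalamus left	THA-L	central
60	Thalamus right	THA-R	central
61	Postcentral gyrus left	PoCG-L	parietal
62	Postcentral gyrus right	PoCG-R	parietal
63	Superior parietal gyrus left	SPG-L	parietal
64	Superior parietal gyrus right	SPG-R	parietal
65	Inferior parietal lobule left	IPL-L	parietal
66	Inferior parietal lobule right	IPL-R	parietal
67	Precuneus left	PCUN-L	parietal
68	Precuneus right	PCUN-R	parietal
69	Paracentral lobule left	PCL-L	frontal
70	Paracentral lobule right	PCL-R	frontal
71	Fusiform gyrus left	FFG-L	temporal
72	Fusiform gyrus right	FFG-R	temporal
73	Pallidum left	PAL-L	temporal
74	Pallidum right	PAL-R	temporal
75	Supramarginal gyrus left	SMG-L	temporal
76	Supramarginal gyrus right	SMG-R	temporal
77	Angular gyrus left	ANG-L	temporal
78	Angular gyrus right	ANG-R	temporal
79	Heschl gyrus left	HES-L	temporal
80	Heschl gyrus right	HES-R	temporal
81	Superior temporal gyrus left	STG-L	temporal
82	Superior temporal gyrus right	STG-R	temporal
83	Temporal pole (superior) left	TPOsup-L	temporal
84	Temporal pole (superior) right	TPOsup-R	temporal
85	Middle temporal gyrus left	MTG-L	temporal
86	Middle temporal gyrus right	MTG-R	temporal
87	Temporal pole (middle) left	TPOmid-L	temporal
88	Temporal pole (middle) right	TPOmid-R	temporal
89	Inferior temporal gyrus left	ITG-L	temporal
90	Inferior temporal gyrus right	ITG-R	temporal
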