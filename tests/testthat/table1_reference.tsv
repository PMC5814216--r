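no	name	sequence	roi_basis	statistic
1	T1CE_PIXEL	T1CE	T1CE	pixel_count
2	T1CE_AREA	T1CE	T1CE	area_cm2
3	T1CE_VOL	T1CE	T1CE	volume_ml
4	T2FLAIR_PIXEL	T2FLAIR	T2FLAIR	pixel_count
5	T2FLAIR_AREA	T2FLAIR	T2FLAIR	area_cm2
6	T2FALIR_VOL	T2FLAIR	T2FLAIR	volume_ml
7	rADCnT1_PIXEL	rADC	T1CE	pixel_count
8	rADCnT1_AREA	rADC	T1CE	area_cm2
9	rADCnT1_VOL	rADC	T1CE	volume_ml
10	rADCnT2_PIXEL	rADC	T2FLAIR	pixel_count
11	rADCnT2_AREA	rADC	T2FLAIR	area_cm2
12	rADCnT2_VOL	rADC	T2FLAIR	volume_ml
13	rCBFnT1_MEAN	rCBF	T1CE	mean
14	rCBFnT1_MEDIAN	rCBF	T1CE	median
15	rCBFnT1_SD	rCBF	T1CE	sd
16	rCBFnT1_X5P	rCBF	T1CE	p5
17	rCBFnT1_X95P	rCBF	T1CE	p95
18	rCBFnT1_Q1	rCBF	T1CE	q1
19	rCBFnT1_Q3	rCBF	T1CE	q3
20	rCBFnT2_MEAN	rCBF	T2FLAIR	mean
21	rCBFnT2_MEDIAN	rCBF	T2FLAIR	median
22	rCBFnT2_SD	rCBF	T2FLAIR	sd
23	rCBFnT2_X5P	rCBF	T2FLAIR	p5
24	rCBFnT2_X95P	rCBF	T2FLAIR	p95
25	rCBFnT2_Q1	rCBF	T2FLAIR	q1
26	rCBFnT2_Q3	rCBF	T2FLAIR	q3
27	rCBVnT1_MEAN	rCBV	T1CE	mean
28	rCBVnT1_MEDIAN	rCBV	T1CE	median
29	rCBVnT1_SD	rCBV	T1CE	sd
30	rCBVnT1_X5P	rCBV	T1CE	p5
31	rCBVnT1_X95P	rCBV	T1CE	p95
32	rCBVnT1_Q1	rCBV	T1CE	q1
33	rCBVnT1_Q3	rCBV	T1CE	q3
34	rCBVnT2_MEAN	rCBV	T2FLAIR	mean
35	rCBVnT2_MEDIAN	rCBV	T2FLAIR	median
36	rCBVnT2_SD	rCBV	T2FLAIR	sd
37	rCBVnT2_X5P	rCBV	T2FLAIR	p5
38	rCBVnT2_X95P	rCBV	T2FLAIR	p95
39	rCBVnT2_Q1	rCBV	T2FLAIR	q1
40	rCBVnT2_Q3	rCBV	T2FLAIR	q3
41	MTTnT1_MEAN	MTT	T1CE	mean
42	MTTnT1_MEDIAN	MTT	T1CE	median
43	MTTnT1_SD	MTT	T1CE	sd
44	MTTnT1_X5P	MTT	T1CE	p5
45	MTTnT1_X95P	MTT	T1CE	p95
46	MTTnT1_Q1	MTT	T1CE	q1
47	MTTnT1_Q3	MTT	T1CE	q3
48	MTTnT2_MEAN	MTT	T2FLAIR	mean
49	MTTnT2_MEDIAN	MTT	T2FLAIR	median
50	MTTnT2_SD	MTT	T2FLAIR	sd
51	MTTnT2_X5P	MTT	T2FLAIR	p5
52	MTTnT2_X95P	MTT	T2FLAIR	p95
53	MTTnT2_Q1	MTT	T2FLAIR	q1
54	MTTnT2_Q3	MTT	T2FLAIR	q3
55	TTPnT1_MEAN	TTP	T1CE	mean
56	TTPnT1_MEDIAN	TTP	T1CE	median
57	TTPnT1_SD	TTP	T1CE	sd
58	TTPnT1_X5P	TTP	T1CE	p5
59	TTPnT1_X95P	TTP	T1CE	p95
60	TTPnT1_Q1	TTP	T1CE	q1
61	TTPnT1_Q3	TTP	T1CE	q3
62	TTPnT2_MEAN	TTP	T2FLAIR	mean
63	TTPnT2_MEDIAN	TTP	T2FLAIR	median
64	TTPnT2_SD	TTP	T2FLAIR	sd
65	TTPnT2_X5P	TTP	T2FLAIR	p5
66	TTPnT2_X95P	TTP	T2FLAIR	p95
67	TTPnT2_Q1	TTP	T2FLAIR	q1
68	TTPnT2_Q3	TTP	T2FLAIR	q3
69	rADCnT1_MEAN	rADC	T1CE	mean
70	rADCnT1_MEDIAN	rADC	T1CE	median
71	rADCnT1_SD	rADC	T1CE	sd
72	rADCnT1_X5P	rADC	T1CE	p5
73	rADCnT1_X95P	rADC	T1CE	p95
74	rADCnT1_Q1	rADC	T1CE	q1
75	rADCnT1_Q3	rADC	T1CE	q3
76	rADCnT2_MEAN	rADC	T2FLAIR	mean
77	rADCnT2_MEDIAN	rADC	T2FLAIR	median
78	rADCnT2_SD	rADC	T2FLAIR	sd
79	rADCnT2_X5P	rADC	T2FLAIR	p5
80	rADCnT2_X95P	rADC	T2FLAIR	p95
81	rADCnT2_Q1	rADC	T2FLAIR	q1
82	rADCnT2_Q3	rADC	T2FLAIR	q3
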