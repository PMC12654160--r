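parameter	treatment	mean	se	letter
pH	CK	8.01	0.03	a
pH	OPT	7.75	0.04	b
pH	OPTN	7.67	0.05	b
pH	OPTP	7.67	0.11	b
pH	OPTM	7.70	0.22	b
SOM	CK	22.23	0.73	c
SOM	OPT	26.57	1.93	b
SOM	OPTN	27.45	2.24	b
SOM	OPTP	26.92	1.34	b
SOM	OPTM	33.16	2.35	a
TN	CK	1.23	0.10	c
TN	OPT	1.42	0.20	b
TN	OPTN	1.39	0.03	bc
TN	OPTP	1.39	0.10	bc
TN	OPTM	1.63	0.04	a
TP	CK	0.67	0.02	c
TP	OPT	0.99	0.05	b
TP	OPTN	1.03	0.15	ab
TP	OPTP	1.15	0.14	a
TP	OPTM	1.09	0.04	ab
AK	CK	82.64	3.74	b
AK	OPT	86.44	4.82	b
AK	OPTN	79.72	8.58	b
AK	OPTP	94.32	23.91	ab
AK	OPTM	111.21	12.84	a
AP	CK	5.77	5.84	d
AP	OPT	48.69	8.85	c
AP	OPTN	39.89	6.07	c
AP	OPTP	92.63	9.03	a
AP	OPTM	62.84	9.53	b
AN	CK	80.30	13.34	b
AN	OPT	95.14	21.95	ab
AN	OPTN	97.04	24.22	ab
AN	OPTP	111.03	6.04	ab
AN	OPTM	123.03	19.79	a
WEOC	CK	151.90	6.54	b
WEOC	OPT	167.86	18.05	ab
WEOC	OPTN	164.67	11.16	ab
WEOC	OPTP	157.79	7.67	b
WEOC	OPTM	180.74	7.89	a
NO3N	CK	1.09	0.07	a
NO3N	OPT	1.08	0.05	a
NO3N	OPTN	1.23	0.24	a
NO3N	OPTP	1.39	0.55	a
NO3N	OPTM	1.33	0.15	a
MBC	CK	261.89	75.36	a
MBC	OPT	320.22	65.78	a
MBC	OPTN	304.03	87.39	a
MBC	OPTP	314.10	91.94	a
MBC	OPTM	307.69	59.11	a
MBN	CK	17.71	8.20	b
MBN	OPT	38.84	6.59	a
MBN	OPTN	39.30	11.71	a
MBN	OPTP	40.28	9.97	a
MBN	OPTM	43.19	6.24	a
MBP	CK	0.35	0.11	b
MBP	OPT	2.41	0.48	a
MBP	OPTN	2.30	0.80	a
MBP	OPTP	0.66	0.25	b
MBP	OPTM	2.05	0.01	a
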