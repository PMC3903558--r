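# taxon_profile: julidan
# provenance: homeotic Ommatoiulus moreleti male with 6 extra pairs of posterior gonopods; left antenna atrophied; single ring equivalent to rings 13+14
# stadium: 10
# podous_rings: 46
# fusion: 13,14
position	side	state	annotation
1	B	WALKING_LEG	.
2	B	WALKING_LEG	.
3	B	WALKING_LEG	.
4	B	WALKING_LEG	.
5	B	WALKING_LEG	.
6	B	WALKING_LEG	.
7	B	WALKING_LEG	.
8	B	ANTERIOR_GONOPOD	.
9	B	POSTERIOR_GONOPOD	.
10	B	POSTERIOR_GONOPOD	ectopic; distorted, foveae empty
11	B	POSTERIOR_GONOPOD	ectopic; distorted, foveae empty
12	B	WALKING_LEG	.
13	B	WALKING_LEG	.
14	B	WALKING_LEG	.
15	B	WALKING_LEG	.
16	B	WALKING_LEG	.
17	B	WALKING_LEG	.
18	B	WALKING_LEG	.
19	B	WALKING_LEG	.
20	B	WALKING_LEG	.
21	B	WALKING_LEG	.
22	B	WALKING_LEG	.
23	B	WALKING_LEG	.
24	B	POSTERIOR_GONOPOD	ectopic; asymmetric, paracoxites reduced
25	B	POSTERIOR_GONOPOD	ectopic; asymmetric, paracoxites reduced
26	B	POSTERIOR_GONOPOD	ectopic; solenomerites of last pair highly reduced
27	B	POSTERIOR_GONOPOD	ectopic; solenomerites of last pair highly reduced
28	B	WALKING_LEG	default_low_confidence
29	B	WALKING_LEG	default_low_confidence
30	B	WALKING_LEG	default_low_confidence
31	B	WALKING_LEG	default_low_confidence
32	B	WALKING_LEG	default_low_confidence
33	B	WALKING_LEG	default_low_confidence
34	B	WALKING_LEG	default_low_confidence
35	B	WALKING_LEG	default_low_confidence
36	B	WALKING_LEG	default_low_confidence
37	B	WALKING_LEG	default_low_confidence
38	B	WALKING_LEG	default_low_confidence
39	B	WALKING_LEG	default_low_confidence
40	B	WALKING_LEG	default_low_confidence
41	B	WALKING_LEG	default_low_confidence
42	B	WALKING_LEG	default_low_confidence
43	B	WALKING_LEG	default_low_confidence
44	B	WALKING_LEG	default_low_confidence
45	B	WALKING_LEG	default_low_confidence
46	B	WALKING_LEG	default_low_confidence
47	B	WALKING_LEG	default_low_confidence
48	B	WALKING_LEG	default_low_confidence
49	B	WALKING_LEG	default_low_confidence
50	B	WALKING_LEG	default_low_confidence
51	B	WALKING_LEG	default_low_confidence
52	B	WALKING_LEG	default_low_confidence
53	B	WALKING_LEG	default_low_confidence
54	B	WALKING_LEG	default_low_confidence
55	B	WALKING_LEG	default_low_confidence
56	B	WALKING_LEG	default_low_confidence
57	B	WALKING_LEG	default_low_confidence
58	B	WALKING_LEG	default_low_confidence
59	B	WALKING_LEG	default_low_confidence
60	B	WALKING_LEG	default_low_confidence
61	B	WALKING_LEG	default_low_confidence
62	B	WALKING_LEG	default_low_confidence
63	B	WALKING_LEG	default_low_confidence
64	B	WALKING_LEG	default_low_confidence
65	B	WALKING_LEG	default_low_confidence
66	B	WALKING_LEG	default_low_confidence
67	B	WALKING_LEG	default_low_confidence
68	B	WALKING_LEG	default_low_confidence
69	B	WALKING_LEG	default_low_confidence
70	B	WALKING_LEG	default_low_confidence
71	B	WALKING_LEG	default_low_confidence
72	B	WALKING_LEG	default_low_confidence
73	B	WALKING_LEG	default_low_confidence
74	B	WALKING_LEG	default_low_confidence
75	B	WALKING_LEG	default_low_confidence
76	B	WALKING_LEG	default_low_confidence
77	B	WALKING_LEG	default_low_confidence
78	B	WALKING_LEG	default_low_confidence
79	B	WALKING_LEG	default_low_confidence
80	B	WALKING_LEG	default_low_confidence
81	B	WALKING_LEG	default_low_confidence
82	B	WALKING_LEG	default_low_confidence
83	B	WALKING_LEG	default_low_confidence
84	B	WALKING_LEG	default_low_confidence
85	B	WALKING_LEG	default_low_confidence
86	B	WALKING_LEG	default_low_confidence
87	B	WALKING_LEG	default_low_confidence
88	B	WALKING_LEG	default_low_confidence
89	B	WALKING_LEG	default_low_confidence
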