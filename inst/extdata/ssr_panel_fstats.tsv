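marker	ht	mean_he	mean_ho	fis	fit	fst	nm
Xcup53	0.86	0.66	0.00	1.00	1.00	0.22	0.84
Xtxp015	0.83	0.67	0.00	1.00	1.00	0.19	1.05
Xisep0310	0.83	0.69	0.35	0.48	0.57	0.16	1.28
Xtxp114	0.71	0.54	0.00	1.00	1.00	0.24	0.77
Xtxp012	0.88	0.79	0.21	0.73	0.76	0.10	2.17
Xtxp273	0.83	0.62	0.14	0.77	0.80	0.25	0.74
Xtxp321	0.78	0.64	0.34	0.46	0.56	0.17	1.14
Xtxp265	0.85	0.67	0.11	0.83	0.86	0.21	0.93
SbAGE01	0.82	0.71	0.00	1.00	1.00	0.13	1.61
Xtxp21	0.82	0.61	0.04	0.93	0.95	0.26	0.70
Xtxp12	0.81	0.73	0.35	0.51	0.55	0.09	2.29
Xtxp3	0.81	0.58	0.04	0.91	0.93	0.28	0.63
Xtxp43	0.85	0.66	0.19	0.70	0.77	0.22	0.84
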