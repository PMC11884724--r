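marker	maf	n	n_alleles	pic	ho	gene_diversity
Xcup53	0.19	91	13	0.85	0.00	0.87
Xtxp015	0.23	91	11	0.82	0.00	0.84
Xisep0310	0.22	91	8	0.80	0.40	0.83
Xtxp114	0.41	91	6	0.68	0.00	0.72
Xtxp012	0.16	91	15	0.88	0.19	0.89
Xtxp273	0.30	91	11	0.78	0.10	0.81
Xtxp321	0.36	91	10	0.71	0.24	0.75
Xtxp265	0.18	91	11	0.86	0.15	0.87
SbAGE01	0.19	91	11	0.84	0.00	0.86
Xtxp21	0.21	91	8	0.82	0.01	0.84
Xtxp12	0.25	91	9	0.79	0.26	0.82
Xtxp3	0.32	91	9	0.76	0.02	0.79
Xtxp43	0.21	91	14	0.83	0.16	0.84
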