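marker	repeat_motif	chromosome	forward_primer	reverse_primer	annealing_c
Xcup53	(TTTA)5	1	GCAGGAGTATAGGCAGAGGC	CGACATGACAAGCTCAAACG	56
Xtxp015	(TC)16	5	CACAAACACTAGTGCCTTATC	CATAGACACCTAGGCCATC	54
Xisep0310	(CCAAT)4	2	TGCCTTGTGCCTTGTTTATCT	GGATCGATGCCTATCTCGTC	57
Xtxp114	(AGG)8	3	CGTCTTCTACCGCGTCCT	CATAATCCCACTCAACAATCC	57
Xtxp012	(CT)22	4	AGATCTGGCGGCAACG	AGTCACCCATCGATCATC	57
Xtxp273	(TTG)20	8	GTACCCATTTAAATTGTTTGCAGTAG	CAGAGGAGGAGGAAGAGAAGG	56
Xtxp321	(GT)4+(AT)6+(CT)21	8	TAACCCAAGCCTGAGCATAAGA	CCCATTCACACATGAGACGAG	60
Xtxp265	(GAA)19	6	GTCTACAGGCGTGCAAATAAAA	TTACCATGCTACCCCTAAAAGTGG	56
SbAGE01	(AG)30	2	GACCGATCTAATGATGCAG	ACGGTAGAGAAGACCCATC	54
Xtxp21	(AG)18	4	GAGCTGCCATAGATTTGGTCG	ACCTCGTCCCACCTTTGTTG	52
Xtxp12	(CT)22	4	AGATCTGGCGGCAACG	AGTCACCCATCGATCATC	56
Xtxp3	(CT)8+(CT)36	2	AGCAGGCGTTTATGGAAG	ATCCTCATACTGCAGGACC	57
Xtxp43	(CT)28	1	AGTCACAGCACACTGCTTGTC	AATTTACCTGGCGCTCTGC	60
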