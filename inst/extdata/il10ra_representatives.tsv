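cluster_id	sequence_id	sequence	r4	r5	rate_printed	kd_nM	category
B	401	CCCCCGCATCACGCCGTGGTGCGATTGACACAATTGCAAT	103513	421606	4.1	25	core
C	402	TCACAGTCCCGGTGCCGCACTAAAACCCATTGTTGTGCGA	37630	149129	4.0	120	core
D	403	TGAGAACTTCTCTCAGTCGGTGGGAGAGTACATCCTAACA	23423	6081	0.3	>500	core
K	406	TAGACGAGCACTTCTCTCAGTCGCATTCATTATTTAAATT	16011	3058	0.2	>500	core
G	407	CCCCTTCCAGCGATTACGATCATTGACTCTCAGTCCTGTG	11789	4679	0.4	>500	core
H	408	ATCGACAGCTCTCAGTCCATTCGAGGAATGTTCATCGATA	5637	1738	0.3	>120	core
J	411	AGCCATGACGATGTCGTTACGTAGATGCAGAGACTCCTAA	3961	6311	1.6	18	core
Z	436	TAACACTCGATTCTCCTAGCCCGCTAGAAATTCCCCTCCC	2513	76374	30.4	65	core
#3	446	AAAGACCGTTTTTTAAAACGCTCAATATACACGACATAAA	89	409	4.6	10	core
#25	454	TGAATCTCGCGCTCGTTGGTACCCTTAAAATAAAGGCATA	742	3147	4.2	8	core
J	411-J-A1G	GGCCATGACGATGTCGTTACGTAGATGCAGAGACTCCTAA	14	47	3.4	9	variant
J	411-J-G7T	AGCCATTACGATGTCGTTACGTAGATGCAGAGACTCCTAA	14	25	2.6	18	variant
J	411-J-A19T	AGCCATGACGATGTCGTTTCGTAGATGCAGAGACTCCTAA	1	2	2	n.d.	variant
J	411-J-C28T	AGCCATGACGATGTCGTTACGTAGATGTAGAGACTCCTAA	2	17	8.5	18	variant
J	411-J-G30T	AGCCATGACGATGTCGTTACGTAGATGCATAGACTCCTAA	9	46	4.9	18	variant
J	411-J-A39G	AGCCATGACGATGTCGTTACGTAGATGCAGAGACTCCTGA	4	5	1.2	n.d.	variant
NA	1BTCIHHiD	TGAAGACTTCTCAGTGCCTCGTCGTACTAAAAACGCAATA	0	3	NA	n.d.	unclustered
NA	1TJjuBP	GCAGCTATCTCACCGAAAGCGTCGCTATATTCGTCGTTAT	1	3	NA	n.d.	unclustered
NA	bystander1	CTATCGCGGCCGATTGTTTCTGCGGACGATGTTGTCCTCA	0	1	NA	n.d.	bystander
NA	bystander2	TAGTTTGGGCATGTTTCCCTTGTAGGTGTGAAACCACTTA	0	1	NA	n.d.	bystander
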