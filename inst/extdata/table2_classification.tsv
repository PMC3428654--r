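# Repeat-type distribution of genic-SSRs in the published sesame
# transcriptome survey (42,566 uni-transcripts): disjoint locus counts by
# classification and unit-size subtype at the >=15 bp and >=18 bp tract
# thresholds.
classification	subtype	n_ge15	n_ge18
perfect	mono	129	21
perfect	di	2592	1764
perfect	tri	1845	770
perfect	tetra	335	78
perfect	penta	652	109
perfect	hexa	932	932
imperfect	mono	82	77
imperfect	di	137	123
imperfect	tri	1	1
compound_perfect	mono-mono	35	22
compound_perfect	di-di	199	193
compound_perfect	tri-tri	4	4
compound_perfect	mono-di	4	3
compound_perfect	mono-tri	2	2
compound_perfect	di-tri	1	1
compound_imperfect	mono-mono	12	12
compound_imperfect	di-di	352	318
compound_imperfect	tri-tri	6	6
compound_imperfect	mono-di	1	1
compound_imperfect	mono-tri	1	1
compound_imperfect	di-tri	2	2
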