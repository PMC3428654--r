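# Headline totals of the published sesame genic-SSR transcriptome survey.
key	value
n_transcripts	42566
total_length_bp	47986977
n_ssrs_ge15	7324
n_ssrs_ge18	4440
n_perfect_ge15	6485
n_perfect_ge18	3674
n_motif_types_ge15	687
n_motif_types_ge18	557
n_primer_pairs	2164
n_markers_screened	300
n_markers_amplified	276
n_polymorphic_markers	32
n_alleles	74
n_accessions	25
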