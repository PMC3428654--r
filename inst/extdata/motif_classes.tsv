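# Counts of the four most abundant canonical motif classes among perfect
# genic-SSRs in the published sesame transcriptome survey, at the >=15 bp
# and >=18 bp thresholds.  display is the survey's family label; class is
# the canonical (lexicographically minimal) representative.
class	display	n_ge15	n_ge18
AG	AG/CT	1733	1268
AC	CA/TG	469	281
AT	AT/AT	390	215
AAG	GAA/TTC	279	131
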