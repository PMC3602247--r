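snp_id	population	source	allele_a	allele_b	n_AA	n_AB	n_BB
rs328	CEU	HAPMAP	C	G	2	27	84
rs328	YRI	HAPMAP	C	G	5	38	70
rs328	EUR	KG	C	G	8	98	273
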