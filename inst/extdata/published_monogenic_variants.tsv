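donor_id	gene	dna_change	protein_change	zygosity	population_frequency	deleteriousness_score
6033	KCNJ11	c.868G>A	Val209Met	Het	0.002	23.5
6166	LMNA	c.898G>A	Asp300Asn	Het	0	28.8
6176	HNF1A	c.29C>T	Thr10Met	Het	0.002	22.2
6243	GLIS3	c.1863C>G	His621Gln	Het	0.001	20.4
6264	INSR	c.3034G>A	Val1012Met	Het	0.80	26.1
6320	GATA6	c.1366C>T	Arg456Cys	Het	0	31
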