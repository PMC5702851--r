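chrom	pos	type	control	gentamicin	neomycin	region	gene	expression_change
chr1	37502	A>G	19.4	43.7	37.0	3UTR	f10	down
chr12	5897211	A>G	39.3	60.8	62.1	3UTR	plekhm1	down
chr12	5897300	A>G	32.8	59.8	59.6	3UTR	plekhm1	down
chr12	5897334	A>G	58.3	79.4	100.0	3UTR	plekhm1	down
chr19	46815419	A>G	10.0	28.6	32.1	3UTR	cu694368.1	down
chr3	55688757	A>G	16.7	32.2	32.3	intron	ubald1b	down
chr6	59149763	A>G	5.8	25.5	40.5	3UTR	shmt2	down
chr7	20754724	A>G	8.7	29.8	25.7	CDS	oxa1l	down
chr16	35895953	A>G	36.1	81.6	71.9	intron	si:dkey-248g17.3	up
chr12	5896131	A>G	46.0	25.0	8.3	3UTR	plekhm1	down
chr12	5897541	A>G	65.1	39.3	30.5	3UTR	plekhm1	down
chr12	26797012	A>G	91.7	72.0	76.4	intron	mta3	down
chr12	26797182	A>G	28.5	12.9	10.6	intron	mta3	down
chr12	26797214	A>G	70.0	53.3	37.5	intron	mta3	down
chr12	26797227	A>G	32.1	7.7	14.1	intron	mta3	down
chr19	46815518	A>G	59.4	18.8	43.8	3UTR	cu694368.1	down
chr20	36940734	C>T	73.2	39.5	45.1	3UTR	cited2	down
chr3	55687706	A>G	51.3	30.7	36.2	intron	ubald1b	down
chr3	55687778	A>G	33.2	16.8	10.8	intron	ubald1b	down
chr15	826092	C>A	63.3	22.0	18.8	CDS	si:dkey-7i4.7	up
chr21	2596180	G>A	54.3	14.3	26.0	3UTR	si:ch211-241b2.1	up
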