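chrom	pos	type	control	gentamicin	neomycin	region	alteration	gene
chr10	2974831	A>G	38.9	66.4	67.6	3UTR	N/A	marveld2a
chr24	40729176	A>G	66.7	90.1	97.9	3UTR	N/A	tbc1d24
chr24	40729155	A>G	66.7	4.5	45.1	3UTR	N/A	tbc1d24
chr21	9763713	A>G	67.5	42.2	50.6	CDS	I/V	bdp1
chr21	9763719	A>G	68.3	44.6	50.0	CDS	M/V	bdp1
chr12	5897211	A>G	39.3	60.8	62.1	3UTR	N/A	plekhm1
chr12	5897300	A>G	32.8	59.8	59.6	3UTR	N/A	plekhm1
chr12	5897334	A>G	58.3	79.4	100.0	3UTR	N/A	plekhm1
chr12	5896131	A>G	46.0	25.0	8.3	3UTR	N/A	plekhm1
chr12	5897541	A>G	65.1	39.3	30.5	3UTR	N/A	plekhm1
chr20	32527617	A>G	56.1	4.2	10.7	3UTR	N/A	ostm1
chr1	27553904	A>G	45.0	19.2	17.7	3UTR	N/A	ednrb1a
chr10	3459366	C>T	88.8	51.1	64.1	3UTR	N/A	ptpn11a
chr13	8739101	G>A	30.6	8.4	15.5	CDS	R/H	alms1
chr13	31129396	G>A	28.6	10.9	10.0	CDS	K/K	ercc6
chr13	46955730	C>T	77.8	52.4	60.6	intron	N/A	fgfr2
chr8	53710690	A>G	61.0	44.5	45.5	3UTR	N/A	fgfr1a
chr8	53711300	A>G	69.4	28.8	45.7	3UTR	N/A	fgfr1a
chr8	53711318	A>G	31.1	12.2	9.4	3UTR	N/A	fgfr1a
chr8	53711323	A>G	30.6	4.2	3.1	3UTR	N/A	fgfr1a
chr12	2152293	A>T	71.7	28.6	53.1	intron	N/A	sox9a
chr12	2152698	G>A	45.6	15.4	22.0	intron	N/A	sox9a
chr8	17101817	A>G	91.7	64.3	69.4	3UTR	N/A	calrl2
chr8	17101934	A>G	74.1	46.7	37.7	3UTR	N/A	calrl2
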