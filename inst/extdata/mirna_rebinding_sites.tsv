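chrom	pos	type	control	gentamicin	neomycin	before_editing	after_editing	gene	expression_change
chr12	5897334	A>G	58.3	79.4	100.0	N/A	dre-miR-726: G|C	plekhm1	down
chr21	2596180	G>A	54.3	14.3	26.0	dre-miR-735-3p: G|C	dre-miR-26a-2-3p: A|U	si:ch211-241b2.1	up
chr6	59149763	A>G	5.8	25.5	40.5	N/A	dre-miR-727-5p: G|C	shmt2	down
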