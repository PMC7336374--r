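chrom	pos	ref	alt	wp_index	mp_index	region_class	orf	mutation_type
chr12	26201284	T	A	0.48	1	Intronic	ORF1	S
chr12	26056055	C	T	0.35	1	Exonic	ORF2	NS
chr12	25512848	C	T	0.35	1	Intronic	ORF3	S
chr12	24400012	G	A	1	1	Intronic	ORF4	S
chr12	23899324	C	T	0.1	1	Intergenic		S
chr12	23818910	C	T	1	1	Downstream	ORF5	S
chr12	18279215	A	C	1	1	Intergenic		S
chr12	17267695	C	G	1	1	Exonic	ORF6	NS
chr12	4148836	G	T	1	1	Intergenic		S
chr12	1935199	C	A	1	1	Intronic	ORF7	S
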