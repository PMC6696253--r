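# Published coding SNP loci of the Saccharum spontaneum (Yunnan 83-184)
# plastome referenced to S. officinarum (Badila). position is 1-based on the
# spliced coding sequence of the gene; codons and amino acids are given for
# the reference (officinarum) and the alternate (spontaneum).
gene_order	gene	position	ref_codon	alt_codon	ref_aa	alt_aa
13	rpoC1	2059	ATA	GTA	I	V
14	rpoC2	3228	GGC	GGT	G	G
19	atpA	572	GGT	GAT	G	D
23	ycf3	300	GCA	GCG	A	A
29	atpB	313	ACT	GCT	T	A
29	atpB	940	GCC	ACC	A	T
38	psbE	57	TAC	TAT	Y	Y
52	rpoA	202	GGG	TGG	G	W
57	rpl14	335	TTT	TAT	F	Y
59	rps3	267	CCC	CCA	P	P
65	ndhB	776	GAC	GGA	D	G
65	ndhB	777	GAC	GGA	D	G
70	ndhF	868	ATA	CTA	I	L
70	ndhF	1804	ATC	CTC	I	L
72	ccsA	537	TTT	TTA	F	L
72	ccsA	538	CTT	AGA	L	R
72	ccsA	539	CTT	AGA	L	R
72	ccsA	540	CTT	AGA	L	R
72	ccsA	939	TAT	TAC	Y	Y
73	ndhD	1240	TTA	GTA	L	V
78	ndhA	858	TCT	TCC	S	S
79	ndhH	793	ATC	GTC	I	V
84	ndhB	776	GAC	GGA	D	G
84	ndhB	777	GAC	GGA	D	G
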