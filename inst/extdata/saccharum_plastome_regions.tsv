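# Published quadripartite region lengths (bp) of the two sugarcane ancestor
# plastomes: S. officinarum Badila (MN204507) and S. spontaneum Yunnan
# 83-184 (MN204508).
species	accession	total	lsc	ssc	irb	ira
officinarum	MN204507	141187	83065	12544	22789	22789
spontaneum	MN204508	141181	83047	12544	22795	22795
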