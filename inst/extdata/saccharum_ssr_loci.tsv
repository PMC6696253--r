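# Published microsatellites (strict preset: 1/10 2/6 3/5 4/5 5/5 6/5) of
# the two sugarcane ancestor plastomes, S. officinarum Badila (MN204507)
# and S. spontaneum Yunnan 83-184 (MN204508). Compound formations are
# decomposed into their constituents (compound column groups them):
# officinarum C1 = (T)10 ctctccta (T)10, 28 bp span;
# spontaneum C2 = (A)10 <45 bp> (A)10, 65 bp span; C3 as C1.
# Coordinates are 1-based inclusive genome positions.
species	motif	repeats	start	end	compound
officinarum	A	13	3754	3766	NA
officinarum	A	11	4114	4124	NA
officinarum	T	10	6446	6455	NA
officinarum	A	11	7777	7787	NA
officinarum	T	10	9056	9065	NA
officinarum	G	10	11003	11012	NA
officinarum	T	11	13372	13382	NA
officinarum	T	13	16556	16568	NA
officinarum	A	10	18659	18668	NA
officinarum	A	12	19205	19216	NA
officinarum	T	12	21069	21080	NA
officinarum	A	10	31914	31923	NA
officinarum	T	11	34093	34103	NA
officinarum	T	10	34862	34871	NA
officinarum	T	10	35824	35833	NA
officinarum	T	10	38697	38706	NA
officinarum	T	10	44257	44266	NA
officinarum	T	14	52367	52380	NA
officinarum	T	10	56710	56719	NA
officinarum	T	10	56892	56901	NA
officinarum	T	10	57363	57372	NA
officinarum	A	11	63551	63561	NA
officinarum	A	11	65513	65523	NA
officinarum	T	10	67486	67495	NA
officinarum	T	11	68139	68149	NA
officinarum	A	10	73938	73947	NA
officinarum	T	12	78482	78493	NA
officinarum	T	10	79044	79053	C1
officinarum	T	10	79062	79071	C1
officinarum	T	14	81260	81273	NA
spontaneum	A	15	3753	3767	NA
spontaneum	A	10	4115	4124	NA
spontaneum	T	11	6112	6122	NA
spontaneum	T	14	6446	6459	NA
spontaneum	A	11	7781	7791	NA
spontaneum	T	10	9060	9069	NA
spontaneum	G	10	11007	11016	NA
spontaneum	T	11	13375	13385	NA
spontaneum	A	10	15948	15957	NA
spontaneum	T	14	16554	16567	NA
spontaneum	A	12	19197	19208	NA
spontaneum	T	10	21061	21070	NA
spontaneum	A	10	31904	31913	NA
spontaneum	T	11	34083	34093	NA
spontaneum	T	10	34852	34861	NA
spontaneum	T	10	35814	35823	NA
spontaneum	T	11	38687	38697	NA
spontaneum	T	11	38836	38846	NA
spontaneum	T	14	52356	52369	NA
spontaneum	T	10	56700	56709	NA
spontaneum	T	10	57351	57360	NA
spontaneum	T	11	60122	60132	NA
spontaneum	T	10	66448	66457	NA
spontaneum	T	10	67465	67474	NA
spontaneum	T	12	68133	68144	NA
spontaneum	A	10	73929	73938	C2
spontaneum	A	10	73984	73993	C2
spontaneum	T	12	78474	78485	NA
spontaneum	T	10	79031	79040	C3
spontaneum	T	10	79049	79058	C3
spontaneum	T	13	81243	81255	NA
spontaneum	A	10	108278	108287	NA
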