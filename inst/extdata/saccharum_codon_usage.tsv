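# Published codon usage of the plastomes of Saccharum officinarum (Badila,
# GenBank MN204507) and S. spontaneum (Yunnan 83-184, MN204508).
# aa: one-letter amino-acid symbol; * = terminator. AUA and GUG appear both
# under their standard amino acid and, as recoded start codons, under Met.
aa	codon	count_officinarum	rscu_officinarum	count_spontaneum	rscu_spontaneum
*	UAA	40	1.579	39	1.520
*	UAG	19	0.750	19	0.740
*	UGA	17	0.671	19	0.740
A	GCA	368	1.198	373	1.192
A	GCC	189	0.615	194	0.62
A	GCG	134	0.436	137	0.438
A	GCU	538	1.751	548	1.751
C	UGC	55	0.498	55	0.491
C	UGU	166	1.502	169	1.509
D	GAC	155	0.437	155	0.433
D	GAU	555	1.563	561	1.567
E	GAA	794	1.497	803	1.484
E	GAG	267	0.503	279	0.516
F	UUC	403	0.718	422	0.732
F	UUU	720	1.282	731	1.268
G	GGA	586	1.570	596	1.567
G	GGC	151	0.404	150	0.394
G	GGG	275	0.737	284	0.747
G	GGU	481	1.289	491	1.291
H	CAC	120	0.512	122	0.501
H	CAU	349	1.488	365	1.499
I	AUA	522	0.956	540	0.970
I	AUC	307	0.562	308	0.553
I	AUU	810	1.483	823	1.478
K	AAA	743	1.450	751	1.437
K	AAG	282	0.550	294	0.563
L	CUA	324	0.894	338	0.910
L	CUC	138	0.380	137	0.369
L	CUG	116	0.320	116	0.313
L	CUU	476	1.313	500	1.346
L	UUA	722	1.992	730	1.966
L	UUG	399	1.100	407	1.096
M	AUA	2	0.013	2	0.013
M	AUG	456	2.961	458	2.961
M	GUG	4	0.026	4	0.026
N	AAC	208	0.515	218	0.527
N	AAU	599	1.485	609	1.473
P	CCA	216	1.013	222	1.026
P	CCC	208	0.975	212	0.979
P	CCG	93	0.436	94	0.434
P	CCU	336	1.576	338	1.561
Q	CAA	524	1.555	532	1.549
Q	CAG	150	0.445	155	0.451
R	AGA	361	1.758	376	1.764
R	AGG	110	0.536	114	0.535
R	CGA	273	1.330	285	1.337
R	CGC	106	0.516	110	0.516
R	CGG	94	0.458	100	0.469
R	CGU	288	1.403	294	1.379
S	AGC	104	0.434	106	0.428
S	AGU	297	1.241	303	1.225
S	UCA	235	0.982	237	0.958
S	UCC	286	1.195	302	1.221
S	UCG	122	0.510	130	0.526
S	UCU	392	1.638	406	1.642
T	ACA	300	1.109	304	1.094
T	ACC	203	0.750	211	0.759
T	ACG	133	0.492	137	0.493
T	ACU	446	1.649	460	1.655
V	GUA	431	1.504	438	1.516
V	GUC	134	0.468	137	0.474
V	GUG	150	0.524	152	0.526
V	GUU	431	1.504	429	1.484
W	UGG	347	1.000	353	1.000
Y	UAC	151	0.411	154	0.410
Y	UAU	583	1.589	598	1.590
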