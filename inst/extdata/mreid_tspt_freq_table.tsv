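locus_id	chrom	allele	p_mreid	p_tspt	printed_diff
S1_45003478	1	C	0.945	0.213	0.732
S2_54669791	2	C	0.250	0.756	-0.506
S2_176020217	2	A	0.798	0.063	0.735
S2_191772106	2	T	0.934	0.263	0.671
S2_198437096	2	T	0.061	0.779	-0.718
S2_226557508	2	C	0.122	0.770	-0.648
S2_226557527	2	G	0.894	0.094	0.800
S3_214980179	3	A	0.775	0.049	0.725
S4_161036243	4	G	0.068	0.838	-0.770
S6_18591062	6	T	0.182	0.867	-0.685
S8_11999061	8	A	0.953	0.230	0.723
S8_15624108	8	G	0.730	0.058	0.672
S8_16258836	8	T	0.061	0.942	-0.881
S8_16278575	8	A	0.078	0.795	-0.717
S10_9987855	10	T	0.865	0.163	0.702
S10_83778123	10	G	0.939	0.244	0.695
S10_141271856	10	C	0.078	0.945	-0.867
S10_144619447	10	G	0.197	0.867	-0.670
S10_144979499	10	G	0.838	0.094	0.744
S10_147013864	10	G	0.881	0.205	0.676
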