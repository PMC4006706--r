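# Published ChIP-seq peak overlap tallies for the 47 e9.5 TGC UR domains:
# number of peaks of each histone mark (called in trophoblast stem cells, TS,
# or in vitro differentiated trophoblast giant cells, TGC) observed to overlap
# a UR domain, versus the expectation from 1,000 TSS-distance- and
# chromosome-preserving randomizations. enrichment is the published ratio
# observed/expected printed at two decimals; all rows significant at p<0.001.
cell	mark	mark_class	observed	expected	enrichment
TS	H3K4me3	active	291	473	0.62
TGC	H3K4me3	active	715	904	0.79
TS	H3K4me1	active	182	3745	0.05
TGC	H3K4me1	active	115	2588	0.04
TS	H3K27ac	active	149	1516	0.10
TGC	H3K27ac	active	67	1826	0.04
TS	H3K9me3	repressive	13183	9122	1.45
TGC	H3K9me3	repressive	6609	5949	1.11
TS	H3K27me3	repressive	3575	2631	1.36
TGC	H3K27me3	repressive	1143	1866	0.61
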