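# Default conserved-site table for the 60-column bHLH motif frame.
# Curated from the canonical basic/helix1/loop/helix2 consensus: charged
# DNA-contacting residues in the basic region, buried hydrophobics in the
# two helices, and the conserved loop positions. The table is editable
# configuration -- the survey accepts any site list -- and site columns are
# 1-based positions in the motif frame.
column	allowed	weight
5	KR	1
9	E	1
10	R	1
12	R	1
13	R	1
16	AVILM	1
19	ILVM	1
20	LMIV	1
23	LIVM	1
27	KRQ	1
36	KR	1
40	STAG	1
45	KR	1
48	AST	1
49	LIVM	1
52	LIVM	1
53	YFH	1
56	LIVM	1
60	LIVM	1
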