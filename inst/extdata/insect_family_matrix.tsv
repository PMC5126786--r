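# Family-by-species bHLH member counts for twelve insect species plus the
# brown planthopper, transcribed verbatim from the published comparison
# table. Species codes: N.l. Nilaparvata lugens; A.p. Acyrthosiphon pisum;
# N.v. Nasonia vitripennis; H.s. Harpegnathos saltator; A.m. Apis mellifera;
# T.c. Tribolium castaneum; L.d. Leptinotarsa decemlineata; B.m. Bombyx
# mori; D.m. Drosophila melanogaster; A.a. Aedes aegypti; A.g. Anopheles
# gambiae; C.q. Culex quinquefasciatus; P.h. Pediculus humanus corporis.
# Note: the N.l. column folds NlMet into the Clock family count and counts
# NlMad under Mad although the gene catalog prints family "Mnt" for it.
family	group	N.l.	A.p.	N.v.	H.s.	A.m.	T.c.	L.d.	B.m.	D.m.	A.a.	A.g.	C.q.	P.h.
ASCa	A	2	0	2	2	2	3	1	4	4	4	2	4	2
ASCb	A	0	1	0	0	0	0	0	0	0	0	0	0	1
MyoD	A	1	0	1	1	1	1	1	1	1	1	1	1	1
E12/E17	A	1	1	1	1	1	1	1	1	1	1	1	1	1
Ngn	A	2	1	1	1	1	1	0	1	1	1	2	2	1
NeuroD	A	0	0	0	0	0	1	0	0	0	1	0	0	0
Atonal	A	3	3	3	3	3	3	2	1	3	5	4	5	3
Mist	A	2	2	2	2	2	1	1	1	1	1	1	1	2
Beta3	A	1	1	1	1	1	1	1	1	1	1	1	1	1
Oligo	A	0	0	0	0	0	0	0	0	0	0	0	0	0
Net	A	1	1	0	1	1	1	1	1	1	1	1	1	1
Delilah	A	3	1	0	0	0	2	1	1	1	1	1	1	1
Mesp	A	1	1	1	1	1	0	0	1	1	1	1	1	1
Twist	A	1	1	1	2	1	1	1	1	1	1	1	1	1
Paraxis	A	1	1	1	1	1	1	1	1	1	1	1	1	0
MyoRa	A	1	1	0	1	1	1	1	1	1	1	1	1	1
MyoRb	A	0	0	0	0	0	0	0	0	0	0	0	0	0
Hand	A	1	1	1	1	1	1	1	1	1	1	1	1	1
PTFa	A	1	1	0	1	1	1	1	1	1	1	2	1	1
PTFb	A	1	2	2	2	1	2	1	1	2	2	2	2	2
SCL	A	1	1	1	1	1	1	1	1	1	1	1	1	1
NSCL	A	1	1	1	1	1	1	1	1	1	1	1	1	1
SRC	B	1	1	1	1	1	1	1	1	1	1	1	1	1
Figα	B	0	0	0	0	0	0	0	0	0	0	0	0	0
Myc	B	1	1	1	1	1	1	1	1	1	1	1	1	1
Mad	B	1	1	1	0	0	1	1	0	0	0	0	0	0
Mnt	B	1	1	1	2	1	1	1	1	1	1	1	1	1
Max	B	1	3	1	2	1	1	1	1	1	1	1	1	1
USF	B	1	1	1	2	2	1	1	1	1	1	1	1	1
MITF	B	1	0	1	1	1	1	1	1	1	1	1	1	2
SREBP	B	3	1	1	1	1	1	1	1	1	1	1	2	1
AP4	B	2	1	2	2	1	1	1	1	1	1	1	1	1
MLX	B	1	1	1	1	1	0	1	1	1	1	1	1	1
TF4	B	1	2	1	1	1	1	1	1	1	1	1	1	1
Clock	C	2	2	2	2	2	2	2	3	3	2	2	2	2
ARNT	C	1	1	1	1	1	1	1	1	1	1	1	1	1
Bmal	C	1	1	1	1	1	1	1	2	1	1	1	1	1
AHR	C	2	2	2	3	2	1	2	3	2	2	2	2	2
Sim	C	2	1	1	1	1	0	1	1	1	1	2	1	1
Trh	C	1	1	1	1	1	1	1	1	1	1	1	2	1
HIF	C	1	1	1	1	1	1	1	1	1	1	1	1	1
Emc	D	1	1	1	1	1	1	1	1	1	1	2	1	1
Hey	E	2	3	2	2	2	2	2	2	2	3	3	3	2
H/E(spl)	E	6	6	4	6	6	6	8	5	11	4	4	4	8
COE	F	2	1	1	1	1	1	1	1	1	1	1	1	1
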