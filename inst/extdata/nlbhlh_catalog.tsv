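# Brown planthopper (N. lugens) bHLH gene catalog, transcribed verbatim from
# the published gene table. Supports are bootstrap percentages (NJ/MP/ML) or
# Bayesian posteriors x100; "n/m" marks a gene that formed no monophyletic
# group with any single reference sequence under that method.
# Transcription notes kept as printed, not normalized:
#  - NlMad is listed with family "Mnt" (homolog ApMad) although the
#    twelve-species count matrix carries a separate one-member Mad family.
#  - NlTrh's Bayesian support is printed as 84 in the table; the running
#    text gives 79. The table value is stored.
#  - Homologs prefixed "?-" were resolved only against the pea-aphid
#    reference set; "?" means unresolved against both reference sets.
gene_name	family	homolog	nj	mp	ml	bayes	gene_id	evidence
NlAse1	ASCa	ase	99	97	87	99		EST
NlAse2	ASCa	ase	99	100	98	68	NLU023528	RT-PCR and EST
NlDa	E12/E17	da	100	100	100	100	NLU002710	RT-PCR and EST
NlNau	MyoD	nau	99	99	95	100	NLU022422	RT-PCR and EST
NlTap1	Ngn	tap	97	91	91	100	NLU007911	RT-PCR and EST
NlTap2	Ngn	tap	97	92	91	100	NLU023195	RT-PCR and EST
NlMistr1	Mist	Mistr	96	89	94	100	NLU012420	RT-PCR and EST
NlMistr2	Mist	Mistr	100	98	98	100	NLU027753	RT-PCR and EST
NlOli	Beta3	Oli	100	100	100	100	NLU011046	RT-PCR and EST
NlCato	Atonal	cato	37	97	78	98	NLU013048	RT-PCR and EST
NlAto1	Atonal	ato	99	88	92	98	NLU020408	RT-PCR and EST
NlAto2	Atonal	ato	98	86	92	98	NLU012608	RT-PCR and EST
NlNet	Net	net	100	99	97	100	NLU003697	EST
NlMyoR	MyoRa	MyoR	99	97	95	100	NLU020439	EST
NlSage	Mesp	sage	100	100	96	100	NLU017450	RT-PCR and EST
NlPxs	Paraxis	Pxs	88	77	80	100		RT-PCR and EST
NlTwi	Twist	twi	98	94	79	100	NLU023739	RT-PCR and EST
NlFer1	PTFa	Fer1	99	92	72	98	NLU018740	RT-PCR and EST
NlFer2	PTFb	Fer2	99	94	65	92	NLU001388	RT-PCR and EST
NlHand	Hand	Hand	98	93	65	97	NLU005290	RT-PCR and EST
NlSCL	SCL	SCL	100	100	99	100	NLU016321	RT-PCR and EST
NlNSCL	NSCL	NSCL	100	99	95	100	NLU009115	EST
NlDel1	Delilah	del	96	91	77	96	NLU025535	RT-PCR and EST
NlDel2	Delilah	del	94	87	78	93	NLU027494	RT-PCR and EST
NlDel3	Delilah	del	94	90	77	95	NLU005401	RT-PCR and EST
NlMnt	Mnt	Mnt	96	88	90	100	NLU002070	RT-PCR and EST
NlMad	Mnt	ApMad	100	100	100	100	NLU010490	RT-PCR and EST
NlMax	Max	Max	99	97	97	100		EST
NlDm	Myc	dm	81	82	97	100	NLU025779	RT-PCR and EST
NlUSF	USF	USF	91	68	94	100	NLU023467	RT-PCR and EST
NlMitif	MITF	Mitif	100	100	100	100	NLU017474	EST
NlCrp1	AP4	Crp	83	44	50	88	NLU016559	EST
NlCrp2	AP4	Crp	98	96	88	100	NLU011530	RT-PCR and EST
NlBmx	TF4	bmx	99	81	98	95		RT-PCR and EST
NlMlx	MLX	MLX	100	97	97	100	NLU009394	RT-PCR and EST
NlSREBP1	SREBP	SREBP	94	73	81	100	NLU005608	EST
NlSREBP2	SREBP	SREBP	96	73	81	100	NLU006435	EST
NlSREBP3	SREBP	SREBP	90	59	72	98	NLU021448	RT-PCR and EST
NlTai	SRC	tai	93	99	100	100	NLU023056	RT-PCR and EST
NlClk	Clock	clk	100	100	98	100	NLU027428	EST
NlDys	AHR	dys	100	100	100	100		RT-PCR and EST
NlSs	AHR	ss	100	100	100	100	NLU022623	EST
NlSim1	Sim	sim	87	79	71	78	NLU022755	RT-PCR and EST
NlSim2	Sim	sim	93	83	72	74	NLU008712	RT-PCR and EST
NlTrh	Trh	trh	99	89	96	84	NLU009957	RT-PCR and EST
NlSima	HIF	sima	79	87	96	100	NLU019462	RT-PCR and EST
NlTgo	ARNT	tgo	100	100	100	100	NLU026318	RT-PCR and EST
NlCyc	Bmal	cyc	97	88	55	86		RT-PCR and EST
NlMet	Met	Met	77	68	77	95		RT-PCR and EST
NlEmc	Emc	emc	93	92	88	100	NLU011228	RT-PCR and EST
NlHey	Hey	Hey	96	89	84	92	NLU027503	RT-PCR and EST
NlStich1	Hey	Stich1	100	100	100	100	NLU010132	EST
NlSide	H/E(spl)	side	97	89	95	100	NLU019226	RT-PCR and EST
NlDpn	H/E(spl)	dpn	61	n/m	21	n/m	NLU021732	RT-PCR and EST
NlH	H/E(spl)	?-ApH	93	93	55	67	NLU017783	RT-PCR and EST
NlE(spl)1	H/E(spl)	?-ApHES1	93	65	62	62	NLU012936	RT-PCR and EST
NlE(spl)2	H/E(spl)	?	n/m	n/m	n/m	n/m	NLU007850	EST
NlE(spl)3	H/E(spl)	?-ApHES1	99	96	85	89	NLU021733	RT-PCR and EST
NlKn(col)1	COE	Kn(col)	100	100	100	100	NLU001955	RT-PCR and EST
NlKn(col)2	COE	Kn(col)	100	100	100	100	NLU011325	RT-PCR and EST
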