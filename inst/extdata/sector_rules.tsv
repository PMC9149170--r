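priority	pattern	field	sector
10	trehalose synth	either	TrSn
11	trehalose-phosphate synthase	either	TrSn
12	tps1	name	TrSn
13	tps2	name	TrSn
14	trehalase	either	TrDg
15	nth1	name	TrDg
16	nth2	name	TrDg
17	ath1	name	TrDg
20	hexose transporter	either	Upt
21	hxt	name	Upt
22	hexokinase	either	Upt
23	glucokinase	either	Upt
24	glk1	name	Upt
30	phosphoglucose isomerase	either	UGlc
31	pgi1	name	UGlc
32	phosphofructokinase	either	UGlc
33	pfk	name	UGlc
40	aldolase	either	LGlc
41	fba1	name	LGlc
42	triosephosphate isomerase	either	LGlc
43	tpi1	name	LGlc
44	glyceraldehyde	either	LGlc
45	tdh	name	LGlc
46	phosphoglycerate	either	LGlc
47	pgk1	name	LGlc
48	gpm1	name	LGlc
49	enolase	either	LGlc
50	eno	name	LGlc
51	pyruvate kinase	either	LGlc
52	cdc19	name	LGlc
60	pyruvate decarboxylase	either	Ferm
61	pdc	name	Ferm
62	alcohol dehydrogenase	either	Ferm
63	adh	name	Ferm
70	glycerol-3-phosphate dehydrogenase	either	Esnk
71	gpd	name	Esnk
72	glycerol-3-phosphatase	either	Esnk
73	gpp	name	Esnk
74	rhr2	name	Esnk
80	oxidative phosphorylation	either	Resp
81	citrate cycle	either	Resp
82	tca cycle	either	Resp
83	atp synthase	either	Resp
84	cytochrome	either	Resp
85	nadh dehydrogenase	either	Resp
86	pyruvate dehydrogenase	either	Resp
87	energy metabolism	label	Resp
90	genetic information processing	label	Grwt
91	ribosom	either	Grwt
95	central carbon metabolism	label	unassigned
99	metabolism	label	Grwt
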