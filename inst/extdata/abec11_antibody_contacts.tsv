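chain	region	residue	resno	probability_pct
HC	CONST	Ser	27	19
HC	CONST	Asn	76	14
HC	CONST	Ser	77	5
HC	CONST	Asn	79	2
HC	CDR1	Gly	28	29
HC	CDR1	Phe	29	53
HC	CDR1	Thr	30	100
HC	CDR1	Ser	32	70
HC	CDR1	Ser	33	98
HC	CDR1	Tyr	34	98
HC	CDR2	His	55	73
HC	CDR3	Phe	102	78
HC	CDR3	Ser	103	90
HC	CDR3	Trp	104	100
HC	CDR3	Arg	105	17
LC	CONST	Tyr	178	80
LC	CONST	Thr	182	98
LC	CONST	Arg	183	93
LC	CONST	Ala	184	58
LC	CONST	Thr	185	85
LC	CONST	Gly	186	68
LC	CONST	Ile	187	43
LC	CONST	Pro	188	63
LC	CONST	Asp	189	85
LC	CDR1	Ser	160	5
LC	CDR2	Gly	179	2
LC	CDR2	Ser	181	37
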