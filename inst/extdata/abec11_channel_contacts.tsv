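protomer	region	residue	resno	probability_pct
P1	EC1	Asn	54	82
P1	EC1	Thr	55	56
P1	EC1	Leu	56	85
P1	EC2	Pro	175	29
P2	EC1	Cys	53	10
P2	EC1	Asn	54	92
P2	EC1	Thr	55	82
P2	EC1	Leu	56	100
P2	EC1	Gln	57	78
P2	EC1	Pro	58	31
P2	EC2	Pro	173	2
P2	EC2	Pro	175	68
P2	EC2	Asn	176	21
P2	EC2	Thr	177	4
P2	EC2	Val	178	2
P3	EC1	Asn	54	63
P3	EC1	Thr	55	7
P3	EC1	Leu	56	100
P3	EC1	Gln	57	65
P3	EC1	Pro	58	7
P3	EC2	Trp	172	12
P3	EC2	Pro	173	7
P3	EC2	Pro	175	43
P3	EC2	Asn	176	56
P3	EC2	Thr	177	68
P4	EC1	Thr	55	2
P4	EC1	Leu	56	85
P4	EC1	Gln	57	90
P4	EC1	Pro	58	73
P4	EC2	Pro	175	14
P4	EC2	Asn	176	5
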