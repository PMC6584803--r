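gene	protein	ec1_54_58	ec2_175_176	note
GJB2	hCx26	NTLQP	PN	reference isoform
GJB6	hCx30	NTLQP	PN	position 177 is Leu; antibody interaction there is mediated by main-chain O/N only (annotation, not used in classification)
GJB1	hCx32	NTLQP	PN	
GJB4	hCx30.3	NTKQP	PH	
GJD3	hCx31.9	NTLQP	PH	
GJA8	hCx50	NTQQP	PN	
GJA3	hCx46	NTQQP	PN	
GJA10	hCx62	NTRQP	PN	
GJB5	hCx31.1	NTRQP	PN	
GJB3	hCx31	NTKQP	PN	
GJA9	hCx59	NTEQP	PN	
GJC2	hCx47	NTRQP	PH	
GJA1	hCx43	NTQQP	PH	
GJA5	hCx40	DTIQP	PH	
GJD4	hCx40.1	NTLQP	TG	
GJC1	hCx45	NTEQP	PH	
GJD2	hCx36	NTLQP	IK	
GJG3	hCx30.2	HTQQP	LG	gene symbol transcribed as printed; functional data elsewhere name this isoform hCx30.2/31.3 (GJC3)
CJB7	hCx25	NSRQP	PN	gene symbol transcribed as printed (CJB7)
GJA4	hCx37	NTAQP	PY	
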