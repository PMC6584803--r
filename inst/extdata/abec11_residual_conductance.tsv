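isoform	residual_pct	source
hCx26	16.8	bundled_literature_value
hCx32	16	bundled_literature_value
hCx30	25	bundled_literature_value
hCx30.2/31.3	91	bundled_literature_value
hCx30.3	82	bundled_literature_value
hCx31	87	bundled_literature_value
hCx31.1	73	bundled_literature_value
hCx37	73	bundled_literature_value
hCx43	73	bundled_literature_value
hCx45	98	bundled_literature_value
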