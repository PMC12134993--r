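name	recognition	cut_top	cut_bottom
AscI	GGCGCGCC	2	6
XhoI	CTCGAG	1	5
SalI	GTCGAC	1	5
NotI	GCGGCCGC	2	6
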