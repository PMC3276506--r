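name	recognition	cut_top	cut_bottom
AvrII	CCTAGG	1	5
HpaI	GTTAAC	3	3
MboI	GATC	0	4
NdeI	CATATG	2	4
StuI	AGGCCT	3	3
EcoRI	GAATTC	1	5
HindIII	AAGCTT	1	5
XhoI	CTCGAG	1	5
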