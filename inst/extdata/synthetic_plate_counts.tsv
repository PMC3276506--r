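strain	phage	titer	replicate
BL21	hybrid	1.0e10	1
BL21	hybrid	1.2e10	2
BL21	hybrid	0.9e10	3
K91	hybrid	8.3e9	1
K91	hybrid	9.6e9	2
K91	hybrid	7.7e9	3
DH5a	hybrid	2.5e9	1
DH5a	hybrid	2.2e9	2
DH5a	hybrid	2.8e9	3
BL21	parentA	1.1e10	1
BL21	parentA	1.0e10	2
BL21	parentA	0.95e10	3
K91	parentA	0	1
K91	parentA	0	2
K91	parentA	0	3
DH5a	parentA	5.4e9	1
DH5a	parentA	6.1e9	2
DH5a	parentA	5.0e9	3
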