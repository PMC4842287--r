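mother	Np	Nm
M04	15	1
M05	2	0
M06	7	3
M07	14	0
M15	10	2
M37	8	1
M40	8	1
M41	15	0
M45	13	0
M47	2	0
M48	14	1
M49	12	2
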