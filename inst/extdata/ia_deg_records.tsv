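symbol	study	comparison	direction	log2fc
BFSP1	Kleinloog	ruptured_vs_unruptured	down	-4.0
BFSP1	Nakaoka	ruptured_vs_unruptured	down	-1.8
CASD1	Kurki	ruptured_vs_unruptured	down	-1.0
CDKN2A	Wang	IA_vs_control	up	NR
CDKN2A	Nakaoka	ruptured_vs_unruptured	down	-1.9
CDKN2B	Wang	IA_vs_control	up	NR
COL1A2	Li	IA_vs_control	up	NR
COL1A2	Wang	IA_vs_control	up	NR
COL3A1	Li	IA_vs_control	up	NR
COL3A1	Wang	IA_vs_control	up	NR
COL5A2	Li	IA_vs_control	up	NR
COL5A2	Shi	IA_vs_control	up	3.3
COL5A2	Wang	IA_vs_control	up	NR
DSTN	Wang	IA_vs_control	down	NR
GULP1	Kurki	ruptured_vs_unruptured	down	-2.2
GULP1	Nakaoka	ruptured_vs_unruptured	down	-1.3
IL6	Kurki	ruptured_vs_unruptured	up	2.2
KLHL7	Nakaoka	ruptured_vs_unruptured	up	0.50
MEOX2	Wang	IA_vs_control	down	NR
MOB4	Wang	IA_vs_control	down	NR
PDK4	Wang	IA_vs_control	down	NR
PDK4	Kurki	ruptured_vs_unruptured	up	1.0
PLCL1	Kleinloog	ruptured_vs_unruptured	down	-4.0
PLCL1	Kurki	ruptured_vs_unruptured	down	-1.4
PPP1R9A	Wang	IA_vs_control	down	NR
RRBP1	Wang	IA_vs_control	up	NR
SGCE	Wang	IA_vs_control	down	NR
SGCE	Kurki	ruptured_vs_unruptured	down	-2.3
SNX5	Wang	IA_vs_control	up	NR
SOX17	Wang	IA_vs_control	down	NR
SOX17	Nakaoka	ruptured_vs_unruptured	up	0.88
TFPI	Wang	IA_vs_control	down	NR
TMEM167A	Kurki	ruptured_vs_unruptured	up	1.2
TOMM7	Kurki	ruptured_vs_unruptured	down	-0.86
VCAN	Shi	IA_vs_control	up	2.9
VCAN	Wang	IA_vs_control	up	NR
XRCC4	Kleinloog	ruptured_vs_unruptured	up	2.3
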