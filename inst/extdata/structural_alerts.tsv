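alert	smarts
nitro	[N+](=O)[O-]
azide	N=[N+]=[N-]
acyl_halide	[CX3](=O)[F,Cl,Br,I]
aldehyde	[CX3H1](=O)[#6]
iso_cyanate_thiocyanate	N=C=[O,S]
epoxide	C1OC1
aziridine	C1NC1
peroxide	[OX2][OX2]
thiol	[SX2H]
hydrazine	[NX3][NX3]
diazo	[NX2]=[NX2]
anhydride	C(=O)OC(=O)
sulfonyl_halide	S(=O)(=O)[F,Cl,Br,I]
michael_acceptor	[CX3]=[CX3][CX3]=[OX1]
quaternary_nitrogen	[N+X4]
phosphorus	[#15]
disulfide	[SX2][SX2]
oxime	[CX3]=[NX2][OX2H1]
thiourea	NC(=S)N
nitroso	[#6][NX2]=[OX1]
alkyl_halide_activated	[CH2X4][Cl,Br,I]
long_aliphatic_chain	[CH2R0][CH2R0][CH2R0][CH2R0][CH2R0][CH2R0][CH2R0]
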