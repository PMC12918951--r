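name	smarts
nitro_group	[NX3](=O)=O
nitro_group_charged	[N+](=O)[O-]
aldehyde	[CX3H1](=O)[#6]
acyl_halide	[CX3](=O)[F,Cl,Br,I]
alkyl_halide	[CX4][Cl,Br,I]
michael_acceptor	[CX3]=[CX3][CX3]=[OX1]
epoxide	C1OC1
aziridine	C1NC1
thiol	[SX2H]
hydrazine	[NX3][NX3]
azo_group	[#6]N=N[#6]
isocyanate	N=C=O
isothiocyanate	N=C=S
peroxide	[OX2][OX2]
thioester	[SX2][CX3]=[OX1]
imine	[CX3]=[NX2][#6]
quaternary_nitrogen	[N+X4]
disulfide	[SX2][SX2]
sulfonyl_halide	S(=O)(=O)[F,Cl,Br,I]
phosphonate_ester	P(=O)(O)O
hydroxamic_acid	C(=O)N[OX2H]
cyanamide	[NX3]C#N
diketone	C(=O)C(=O)
carbazide	NNC(=O)NN
hydantoin	C1C(=O)NC(=O)N1
oxime	[CX3]=N[OX2H]
enamine	[CX3]=[CX3][NX3]
nitroso	[#6]N=O
triphenyl_methyl	C(c1ccccc1)(c1ccccc1)c1ccccc1
polyene	C=CC=CC=C
three_membered_heterocycle_S	C1SC1
crown_ether_fragment	OCCOCCOCCO
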