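name	smarts
quinone_A	O=C1C=CC(=O)C=C1
quinone_B	O=C1C(=O)C=CC=C1
catechol_A	c1cc([OX2H])c([OX2H])cc1
hydroquinone_A	[OX2H]c1ccc([OX2H])cc1
rhodanine_A	S=C1NC(=O)CS1
ene_rhodanine_A	S=C1NC(=O)C(=C)S1
alkylidene_barbiturate	O=C1NC(=O)NC(=O)C1=C
hydroxyphenyl_hydrazone	[OX2H]c1ccccc1C=NN
azo_aromatic	c1ccccc1N=Nc1ccccc1
mannich_phenol	[OX2H]c1ccccc1C[NX3]
ene_one_ene	C=CC(=O)C=C
imine_phenol	[OX2H]c1ccccc1C=N
anil_di_alk	c1ccc(cc1)N(C)C=C
thiophene_amino	Nc1cccs1
styrene_sulfonamide	C=Cc1ccccc1S(=O)(=O)N
beta_keto_anilide	O=C(C)C(=O)Nc1ccccc1
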