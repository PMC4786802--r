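smarts	id	family
[CX3](=[OX1])[Cl,Br,I]	acyl_halide	reactive
[SX4](=[OX1])(=[OX1])[F,Cl,Br]	sulfonyl_halide	reactive
[CX3H1](=[OX1])[#6]	aldehyde	reactive
[CX4;!$(C(F)(F)F)][Cl,Br,I]	alkyl_halide	reactive
[OX2r3]1[#6r3][#6r3]1	epoxide	reactive
[NX3r3]1[#6r3][#6r3]1	aziridine	reactive
[NX2]=[CX2]=[OX1]	isocyanate	reactive
[NX2]=[CX2]=[SX1]	isothiocyanate	reactive
[CX3](=[OX1])[OX2][CX3](=[OX1])	anhydride	reactive
[NX1]#[NX2][#6]	diazonium	reactive
[NX2]=[NX2+]=[NX1-]	azide	reactive
[OX2][OX2]	peroxide	reactive
[CX3]=[CX3][CX3](=[OX1])[#6]	michael_acceptor	warhead
[CX3](=[OX1])[CX4][Cl,Br,I]	alpha_halo_ketone	warhead
[SX2][SX2]	disulfide	warhead
C=[CX3][SX4](=[OX1])(=[OX1])	vinyl_sulfone	warhead
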