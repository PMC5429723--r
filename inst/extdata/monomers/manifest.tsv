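residue	file	upstream_atom	downstream_main	downstream_branch	link_length	link_angle	formal_charge	version
GAL	gal.pdb	C1	O4	O6	1.43	109.5	0	1
RHA	rha.pdb	C1	O4		1.43	109.5	0	1
GLA	gla.pdb	C1	O4	O2	1.43	109.5	-1	1
ARA	ara.pdb	C1	O5		1.43	109.5	0	1
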