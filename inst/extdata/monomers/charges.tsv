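residue	name	charge
GAL	C1	0.45
GAL	C2	0.15
GAL	C3	0.15
GAL	C4	0.15
GAL	C5	0.15
GAL	O5	-0.4
GAL	O1	-0.65
GAL	HO1	0.42
GAL	O2	-0.65
GAL	HO2	0.42
GAL	O3	-0.65
GAL	HO3	0.42
GAL	O4	-0.65
GAL	HO4	0.42
GAL	H1	0.05
GAL	H2	0.05
GAL	H3	0.05
GAL	H4	0.05
GAL	H5	0.05
GAL	C6	0.15
GAL	H61	0.05
GAL	H62	0.05
GAL	O6	-0.65
GAL	HO6	0.42
RHA	C1	0.17
RHA	C2	0.15
RHA	C3	0.15
RHA	C4	0.15
RHA	C5	0.15
RHA	O5	-0.4
RHA	O1	-0.65
RHA	HO1	0.42
RHA	O2	-0.65
RHA	HO2	0.42
RHA	O3	-0.65
RHA	HO3	0.42
RHA	O4	-0.65
RHA	HO4	0.42
RHA	H1	0.05
RHA	H2	0.05
RHA	H3	0.05
RHA	H4	0.05
RHA	H5	0.05
RHA	C6	0.15
RHA	H61	0.05
RHA	H62	0.05
RHA	H63	0.05
GLA	C1	0.45
GLA	C2	0.15
GLA	C3	0.15
GLA	C4	0.15
GLA	C5	0.15
GLA	O5	-0.4
GLA	O1	-0.65
GLA	HO1	0.42
GLA	O2	-0.65
GLA	HO2	0.42
GLA	O3	-0.65
GLA	HO3	0.42
GLA	O4	-0.65
GLA	HO4	0.42
GLA	H1	0.05
GLA	H2	0.05
GLA	H3	0.05
GLA	H4	0.05
GLA	H5	0.05
GLA	C6	0.62
GLA	O6A	-0.8
GLA	O6B	-0.8
ARA	C1	0.17
ARA	C2	0.15
ARA	C3	0.15
ARA	C4	0.15
ARA	O4	-0.4
ARA	O1	-0.65
ARA	HO1	0.42
ARA	O2	-0.65
ARA	HO2	0.42
ARA	O3	-0.65
ARA	HO3	0.42
ARA	C5	0.15
ARA	O5	-0.4
ARA	HO5	0.42
ARA	H1	0.05
ARA	H2	0.05
ARA	H3	0.05
ARA	H4	0.05
ARA	H51	0.05
ARA	H52	0.05
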