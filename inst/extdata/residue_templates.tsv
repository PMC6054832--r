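resname	atom	donor	acceptor	cation	anion	ring
ARG	NE	1	0	1	0	-
ARG	NH1	1	0	1	0	-
ARG	NH2	1	0	1	0	-
LYS	NZ	1	0	1	0	-
HIS	ND1	1	1	0	0	IM
HIS	NE2	1	1	0	0	IM
HIS	CG	0	0	0	0	IM
HIS	CD2	0	0	0	0	IM
HIS	CE1	0	0	0	0	IM
ASP	OD1	0	1	0	1	-
ASP	OD2	0	1	0	1	-
GLU	OE1	0	1	0	1	-
GLU	OE2	0	1	0	1	-
ASN	OD1	0	1	0	0	-
ASN	ND2	1	0	0	0	-
GLN	OE1	0	1	0	0	-
GLN	NE2	1	0	0	0	-
SER	OG	1	1	0	0	-
THR	OG1	1	1	0	0	-
CYS	SG	1	0	0	0	-
TYR	OH	1	1	0	0	-
TYR	CG	0	0	0	0	AR
TYR	CD1	0	0	0	0	AR
TYR	CD2	0	0	0	0	AR
TYR	CE1	0	0	0	0	AR
TYR	CE2	0	0	0	0	AR
TYR	CZ	0	0	0	0	AR
PHE	CG	0	0	0	0	AR
PHE	CD1	0	0	0	0	AR
PHE	CD2	0	0	0	0	AR
PHE	CE1	0	0	0	0	AR
PHE	CE2	0	0	0	0	AR
PHE	CZ	0	0	0	0	AR
TRP	NE1	1	0	0	0	P5
TRP	CG	0	0	0	0	P5
TRP	CD1	0	0	0	0	P5
TRP	CD2	0	0	0	0	P5,B6
TRP	CE2	0	0	0	0	P5,B6
TRP	CE3	0	0	0	0	B6
TRP	CZ2	0	0	0	0	B6
TRP	CZ3	0	0	0	0	B6
TRP	CH2	0	0	0	0	B6
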