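# Residue/atom-name rules for the eight pharmacophoric protein channels.
# Channels: hydrophobic, aromatic, acceptor, donor, positive, negative,
# metal, excluded.  The excluded-volume channel is set on every heavy atom
# and is not listed here.  Carbon atoms of known residues default to
# hydrophobic; aromatic ring carbons listed below additionally get the
# aromatic flag.  Metal elements are flagged metallic by element.  A residue
# of "*" matches any standard residue (backbone atoms).
residue	atom	channels
*	N	donor
*	O	acceptor
*	OXT	acceptor
ARG	NE	donor,positive
ARG	NH1	donor,positive
ARG	NH2	donor,positive
ARG	CZ	positive
ASN	OD1	acceptor
ASN	ND2	donor
ASP	OD1	acceptor,negative
ASP	OD2	acceptor,negative
CYS	SG	donor
GLN	OE1	acceptor
GLN	NE2	donor
GLU	OE1	acceptor,negative
GLU	OE2	acceptor,negative
HIS	ND1	acceptor,donor
HIS	NE2	acceptor,donor
HIS	CG	aromatic
HIS	CD2	aromatic
HIS	CE1	aromatic
LYS	NZ	donor,positive
MET	SD	acceptor
PHE	CG	aromatic
PHE	CD1	aromatic
PHE	CD2	aromatic
PHE	CE1	aromatic
PHE	CE2	aromatic
PHE	CZ	aromatic
SER	OG	acceptor,donor
THR	OG1	acceptor,donor
TRP	NE1	donor
TRP	CG	aromatic
TRP	CD1	aromatic
TRP	CD2	aromatic
TRP	CE2	aromatic
TRP	CE3	aromatic
TRP	CZ2	aromatic
TRP	CZ3	aromatic
TRP	CH2	aromatic
TYR	OH	acceptor,donor
TYR	CG	aromatic
TYR	CD1	aromatic
TYR	CD2	aromatic
TYR	CE1	aromatic
TYR	CE2	aromatic
TYR	CZ	aromatic
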