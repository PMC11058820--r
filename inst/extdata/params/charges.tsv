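# tcrm reduced partial-charge set, version 1.0
# Formal charges on ionizable side chains (His neutral at pH 7) plus a small
# backbone amide dipole; resid "*" matches every residue. Hydrogens are not
# modeled, so charges sit on the heavy atoms that carry them.
resid	elety	charge
*	N	0.25
*	O	-0.25
*	OXT	-0.50
ASP	OD1	-0.50
ASP	OD2	-0.50
GLU	OE1	-0.50
GLU	OE2	-0.50
LYS	NZ	1.00
ARG	NE	0.20
ARG	NH1	0.40
ARG	NH2	0.40
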