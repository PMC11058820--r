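# tcrm Lennard-Jones atom-class parameters, version 1.0
# rmin2 = Rmin/2 per atom (A); pair Rmin = rmin2_i + rmin2_j; epsilon in
# kcal/mol combined geometrically. United heavy-atom values.
class	rmin2	epsilon
C	2.00	0.090
N	1.85	0.170
O	1.70	0.120
S	2.00	0.400
P	2.10	0.400
X	1.90	0.100
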