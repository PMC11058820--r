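# tcrm Lazaridis-Karplus solvation parameters, version 1.0
# dgfree kcal/mol, lambda A (correlation length), volume A^3.
class	dgfree	lambda	volume
C	0.60	3.5	14.7
N	-6.00	3.5	11.2
O	-6.00	3.5	10.8
S	-2.00	3.5	14.7
P	-4.00	3.5	14.0
X	0.00	3.5	14.0
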