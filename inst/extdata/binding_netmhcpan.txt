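# NetMHCpan-style output (synthetic example rows)
Pos	MHC	Peptide	%Rank_EL	Aff(nM)
1	HLA-A*02:01	KLDETFFYV	0.12	45.0
2	HLA-A02:01	SLYNTVATL	1.00	820.0
3	HLA-B*07:02	APRGPHGGA	5.00	15000.0
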