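patient_id	chrom	pos	ref	alt	gene	variant_class	alt_count	depth
P01	12	25245350	G	A	KRAS	missense	30	100
P01	17	7674220	C	T	TP53	nonsense	22	88
P01	4	1803568	G	GTT	FGFR3	frameshift_ins	15	60
P01	14	105246551	A	G	AKT1	silent	41	120
P01	2	212578380	T	C	ERBB4	missense	0	0
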