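##fileformat=VCFv4.2
##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">
##FORMAT=<ID=AD,Number=R,Type=Integer,Description="Allelic depths">
##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">
#CHROM	POS	ID	REF	ALT	QUAL	FILTER	INFO	FORMAT	NORMAL	TUMOR
12	25245350	.	G	A	100	PASS	.	GT:AD:DP	0/0:98,1:99	0/1:70,30:100
17	7674220	.	C	T	90	PASS	.	GT:AD:DP	0/0:85,0:85	0/1:66,22:88
4	1803568	.	G	GTT	80	PASS	.	GT:AD:DP	0/0:60,0:60	0/1:45,15:60
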