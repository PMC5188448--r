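##fileformat=VCFv4.2
##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">
#CHROM	POS	ID	REF	ALT	QUAL	FILTER	INFO	FORMAT	S00001	S00002	S00003
10	114758349	rs7903146	C	T	.	PASS	.	GT	0/1	0/1	0/0
3	185511687	rs4402960	G	T	.	PASS	.	GT	0/0	0/1	1/1
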