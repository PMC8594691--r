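##fileformat=VCFv4.2
##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">
#CHROM	POS	ID	REF	ALT	QUAL	FILTER	INFO	FORMAT	S1	S2	S3	S4
contig01	120	.	C	T	60	PASS	.	GT	0/0	0/1	0/1	0/1
contig01	300	.	C	T	60	PASS	.	GT	0/0	0/1	0/1	1/1
contig01	650	.	C	T	60	PASS	.	GT	1/1	0/1	0/1	0/0
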