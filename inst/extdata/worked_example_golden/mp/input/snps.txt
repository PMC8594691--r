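snp	S1	S2	S3	S4
contig01:120	1	2	2	2
contig01:300	1	2	2	3
contig01:650	3	2	2	1
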