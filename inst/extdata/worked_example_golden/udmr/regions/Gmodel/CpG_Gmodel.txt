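ID	snp	beta	stats	pvalue	FDR
contig01:90-500	contig01:120	0.02	1	0.5	0.942284123
contig01:600-700	contig01:120	-0.05	-0.833333333	0.557715877	0.942284123
contig01:600-700	contig01:300	0.005	0.0909090909	0.942284123	0.942284123
contig01:600-700	contig01:650	-0.005	-0.0909090909	0.942284123	0.942284123
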