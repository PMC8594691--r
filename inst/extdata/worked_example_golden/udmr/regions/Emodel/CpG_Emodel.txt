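ID	beta	stats	pvalue	FDR
contig01:90-500	0.02	60740010	1.04810614e-08	2.09621227e-08
contig01:600-700	0.005	0.0909090909	0.942284123	0.942284123
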