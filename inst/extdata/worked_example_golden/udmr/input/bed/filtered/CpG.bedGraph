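chrom	start	end	S1	S2	S3	S4
contig01	90	500	0.414285714	0.434285714	0.447142857	0.467142857
contig01	600	700	0.55	0.5	0.52	0.58
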