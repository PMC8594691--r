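chrom	start	end	S1	S2	S3	S4
contig01	100	101	0.1	0.2	0.3	0.42
contig01	150	151	0.5	0.52	0.46	0.5
contig01	200	201	0.8	0.74	0.82	0.78
contig01	260	261	0.2	0.26	0.22	0.16
contig01	320	321	0.6	0.58	0.61	0.65
contig01	400	401	0.4	0.46	0.36	0.44
contig01	480	481	0.3	0.28	0.36	0.32
contig01	560	561	0.7	0.73	0.66	0.64
contig01	640	641	0.55	0.5	0.52	0.58
contig01	720	721	0.25	0.28	0.22	0.26
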