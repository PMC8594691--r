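contig01	100	101	42	8	12
contig01	150	151	50	10	10
contig01	200	201	78	16	4
contig01	260	261	16	3	17
contig01	320	321	65	13	7
contig01	400	401	44	9	11
contig01	480	481	32	6	14
contig01	560	561	64	13	7
contig01	640	641	58	12	8
contig01	720	721	26	5	15
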