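contig01	100	101	30	6	14
contig01	150	151	46	9	11
contig01	200	201	82	16	4
contig01	260	261	22	4	16
contig01	320	321	61	12	8
contig01	400	401	36	7	13
contig01	480	481	36	7	13
contig01	560	561	66	13	7
contig01	640	641	52	10	10
contig01	720	721	22	4	16
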