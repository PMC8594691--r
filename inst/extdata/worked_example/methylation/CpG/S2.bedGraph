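contig01	100	101	20	4	16
contig01	150	151	52	10	10
contig01	200	201	74	15	5
contig01	260	261	26	5	15
contig01	320	321	58	12	8
contig01	400	401	46	9	11
contig01	480	481	28	6	14
contig01	560	561	73	15	5
contig01	640	641	50	10	10
contig01	720	721	28	6	14
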