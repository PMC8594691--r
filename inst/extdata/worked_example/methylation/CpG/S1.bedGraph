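contig01	100	101	10	2	18
contig01	150	151	50	10	10
contig01	200	201	80	16	4
contig01	260	261	20	4	16
contig01	320	321	60	12	8
contig01	400	401	40	8	12
contig01	480	481	30	6	14
contig01	560	561	70	14	6
contig01	640	641	55	11	9
contig01	720	721	25	5	15
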