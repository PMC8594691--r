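ID	beta	stats	pvalue	FDR
contig01:100-101	0.11	11	0.0577158768	0.301114902
contig01:150-151	0.03	3	0.204832765	0.341387941
contig01:200-201	-0.05	-5	0.125665916	0.314164791
contig01:260-261	1.73472348e-17	2.89120579e-16	1	1
contig01:320-321	0.01	0.333333333	0.795167235	1
contig01:400-401	0.07	7	0.0903344706	0.301114902
contig01:480-481	-0.03	-3	0.204832765	0.341387941
contig01:560-561	0.005	0.2	0.874334084	1
contig01:640-641	0.005	0.0909090909	0.942284123	1
contig01:720-721	0.035	7	0.0903344706	0.301114902
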