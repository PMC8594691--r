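ID	snp	beta	stats	pvalue	FDR
contig01:100-101	contig01:120	0.1	0.833333333	0.557715877	0.932107059
contig01:100-101	contig01:300	0.11	11	0.0577158768	0.451672353
contig01:100-101	contig01:650	-0.11	-11	0.0577158768	0.451672353
contig01:150-151	contig01:120	0.02	0.5	0.704832765	0.961135588
contig01:150-151	contig01:300	0.03	3	0.204832765	0.512081912
contig01:150-151	contig01:650	-0.03	-3	0.204832765	0.512081912
contig01:200-201	contig01:120	-0.06	-1.5	0.374334084	0.802144465
contig01:200-201	contig01:300	-0.05	-5	0.125665916	0.471247186
contig01:200-201	contig01:650	0.05	5	0.125665916	0.471247186
contig01:260-261	contig01:120	0.06	1	0.5	0.932107059
contig01:260-261	contig01:300	6.9388939e-18	1.15648232e-16	1	1
contig01:260-261	contig01:650	-2.77555756e-17	-4.62592927e-16	1	1
contig01:320-321	contig01:120	-0.02	-0.5	0.704832765	0.961135588
contig01:320-321	contig01:300	0.01	0.333333333	0.795167235	0.993959044
contig01:320-321	contig01:650	-0.01	-0.333333333	0.795167235	0.993959044
contig01:400-401	contig01:120	0.06	0.75	0.590334471	0.932107059
contig01:400-401	contig01:300	0.07	7	0.0903344706	0.451672353
contig01:400-401	contig01:650	-0.07	-7	0.0903344706	0.451672353
contig01:480-481	contig01:120	-0.02	-0.5	0.704832765	0.961135588
contig01:480-481	contig01:300	-0.03	-3	0.204832765	0.512081912
contig01:480-481	contig01:650	0.03	3	0.204832765	0.512081912
contig01:560-561	contig01:120	0.03	1.5	0.374334084	0.802144465
contig01:560-561	contig01:300	0.005	0.2	0.874334084	1
contig01:560-561	contig01:650	-0.005	-0.2	0.874334084	1
contig01:640-641	contig01:120	-0.05	-0.833333333	0.557715877	0.932107059
contig01:640-641	contig01:300	0.005	0.0909090909	0.942284123	1
contig01:640-641	contig01:650	-0.005	-0.0909090909	0.942284123	1
contig01:720-721	contig01:120	0.03	0.75	0.590334471	0.932107059
contig01:720-721	contig01:300	0.035	7	0.0903344706	0.451672353
contig01:720-721	contig01:650	-0.035	-7	0.0903344706	0.451672353
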