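sample	cov1south	env
S1	0	1
S2	0	2
S3	1	3
S4	1	4
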