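sample	cov1south
S1	0
S2	0
S3	1
S4	1
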