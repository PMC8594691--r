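S1	1	north
S2	2	north
S3	3	south
S4	4	south
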