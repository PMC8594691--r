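contig01	140	340
contig01	600	700
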