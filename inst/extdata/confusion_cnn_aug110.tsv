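RHT	LHT	FT
9	1	0
0	10	0
0	0	10
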