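RHT	LHT	FT
8	1	1
2	7	1
0	1	9
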