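node_a	node_b	confidence
A	B	0.2242
A	C	0.0460
A	D	0.8935
B	C	0.3921
B	D	0.7689
C	D	0.9439
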