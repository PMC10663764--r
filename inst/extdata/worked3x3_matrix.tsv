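id	a	b	c
a	1	5	6
b	4	2	7
c	8	9	3
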