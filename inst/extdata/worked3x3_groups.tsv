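object_id	group_label
a	g1
b	g2
c	g3
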