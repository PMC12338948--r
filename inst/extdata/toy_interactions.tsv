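hap_a	hap_b	weight
H1	H1	2
H1	H2	1.2
H3	H3	-1
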