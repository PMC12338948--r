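geno_a	geno_b	weight
0	0	0
0	1	1.8
0	2	3.2
1	0	1.5
1	1	4.5
1	2	3.9
2	0	2.8
2	1	3.8
2	2	3.4
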