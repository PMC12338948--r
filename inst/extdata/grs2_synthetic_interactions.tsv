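hap_a	hap_b	weight
DR3	DR4_DQ8	4.5
DR3	DR3	3.4
DR4_DQ8	DR4_DQ8	3.8
DR3	DR4_DQ7	2.2
DR4_DQ8	DR4_DQ7	2.4
DR4_DQ8	DR8_DQ4	2.8
DR3	DR9_DQ9	2.5
DR4_DQ8	DR9_DQ9	2.3
DR4_DQ8	DR1_DQ5	2.1
DR3	DR1_DQ5	1.6
DR4_DQ7	DR4_DQ7	1.4
DR8_DQ4	DR8_DQ4	1.1
DR15_DQ6	DR15_DQ6	-4.1
DR15_DQ6	DR3	-1.8
DR15_DQ6	DR4_DQ8	-1.3
DR7_DQ2	DR7_DQ2	-1.5
DR13_DQ6	DR13_DQ6	-1.1
DR11_DQ7	DR11_DQ7	-1
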