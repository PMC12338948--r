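haplotype	uganda	cameroon	us_african	us_european	us_hispanic
DR3	0.0839	0.087	0.0919	0.1245	0.11
DR4_DQ8	0.0761	0.0789	0.0834	0.1133	0.1
DR4_DQ7	0.0375	0.039	0.0413	0.0571	0.05
DR15_DQ6	0.1678	0.1623	0.1543	0.115	0.13
DR7_DQ2	0.1304	0.126	0.1195	0.0881	0.1
DR8_DQ4	0.0149	0.0155	0.0164	0.0229	0.02
DR11_DQ7	0.0793	0.0765	0.0723	0.0526	0.06
DR13_DQ6	0.0793	0.0765	0.0723	0.0526	0.06
DR1_DQ5	0.0683	0.0709	0.0749	0.1021	0.09
DR9_DQ9	0.0089	0.0093	0.0098	0.0138	0.012
DR10_DQ5	0.01	0.01	0.01	0.01	0.01
DR14_DQ5	0.03	0.03	0.03	0.03	0.03
DR16_DQ5	0.02	0.02	0.02	0.02	0.02
DR12_DQ7	0.02	0.02	0.02	0.02	0.02
OTHER	0.1736	0.1781	0.1839	0.178	0.188
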