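variant_id	chrom	pos	effect_allele	other_allele	weight	region	role	haplotype_name
rs1	6	100	A	G	0	hla_tag	haplotype_tag	H1
rs2	6	200	C	T	0	hla_tag	haplotype_tag	H2
rs3	6	300	G	A	0	hla_tag	haplotype_tag	H3
rs4	6	1000	T	C	0.8	hla_other	linear	NA
rs5	6	2000	A	G	-0.5	hla_other	linear	NA
rs6	1	500	C	T	0.6	non_hla	linear	NA
rs7	2	600	G	A	0.3	non_hla	linear	NA
rs8	3	700	T	C	-0.2	non_hla	linear	NA
rs9	4	800	A	G	0.4	non_hla	linear	NA
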