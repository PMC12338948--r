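variant_id	chrom	pos	effect_allele	other_allele	weight	region	role	haplotype_name
rs2187668	6	32638107	T	C	1.7	hla_tag	linear	NA
rs7454108	6	32693976	G	C	1.9	hla_tag	linear	NA
rs9273363	6	32658525	A	T	-1.9	hla_tag	linear	NA
rs9224084	6	32904760	G	A	0.479	hla_other	linear	NA
rs9270014	6	32046947	C	T	0.462	hla_other	linear	NA
rs689	11	2160994	C	A	0.45	non_hla	linear	NA
rs2476601	1	113834946	C	G	0.3	non_hla	linear	NA
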