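variant_id	chrom	pos	effect_allele	other_allele	weight	region	role	haplotype_name
rs2187668	6	32638107	T	C	0	hla_tag	combination	NA
rs7454108	6	32693976	G	C	0	hla_tag	combination	NA
rs9235779	6	30048660	A	C	0.308	hla_other	linear	NA
rs9232917	6	30201703	A	T	0.297	hla_other	linear	NA
rs9254042	6	30799359	C	G	0.26	hla_other	linear	NA
rs9244980	6	30825728	G	A	0.341	hla_other	linear	NA
rs9247333	6	31027422	T	A	-0.143	hla_other	linear	NA
rs9210072	6	31146771	G	C	0.194	hla_other	linear	NA
rs9281640	6	31233136	G	A	0.181	hla_other	linear	NA
rs9268045	6	31294338	C	T	0.173	hla_other	linear	NA
rs9217494	6	31354861	A	T	-0.283	hla_other	linear	NA
rs9293639	6	31483745	T	A	0.404	hla_other	linear	NA
rs689	11	2160994	C	A	0.376	non_hla	linear	NA
rs2476601	1	113834946	C	G	0.212	non_hla	linear	NA
rs6634240	14	143573062	T	A	0.076	non_hla	linear	NA
rs6673691	8	39157124	G	A	-0.092	non_hla	linear	NA
rs6622316	19	175822868	T	C	0.054	non_hla	linear	NA
rs6655359	21	78739123	A	T	-0.067	non_hla	linear	NA
rs6673564	22	67073940	G	T	0.197	non_hla	linear	NA
rs6665540	11	156340217	G	A	0.15	non_hla	linear	NA
rs6616219	18	114169356	C	T	0.05	non_hla	linear	NA
rs6610463	13	203884826	A	T	0.127	non_hla	linear	NA
rs6646931	17	138916497	A	T	-0.143	non_hla	linear	NA
rs6649587	10	222678467	T	C	0.244	non_hla	linear	NA
rs6683277	20	139075953	A	C	0.164	non_hla	linear	NA
rs6696948	4	37393459	T	A	0.166	non_hla	linear	NA
rs6613882	22	157683834	C	T	-0.211	non_hla	linear	NA
rs6619981	14	213464228	C	A	0.101	non_hla	linear	NA
rs6660731	17	168988531	G	T	-0.118	non_hla	linear	NA
rs6697898	19	113211224	G	T	0.124	non_hla	linear	NA
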