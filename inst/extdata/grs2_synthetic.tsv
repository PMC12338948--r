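variant_id	chrom	pos	effect_allele	other_allele	weight	region	role	haplotype_name
rs17426593	6	32474286	C	A	0	hla_tag	haplotype_tag	DR4_DQ7
rs28746898	6	32494440	A	T	0	hla_tag	haplotype_tag	DR7_DQ2
rs7775228	6	32565584	C	T	0	hla_tag	haplotype_tag	DR8_DQ4
rs1281934	6	32628808	T	C	0	hla_tag	haplotype_tag	DR11_DQ7
rs2187668	6	32638107	T	C	0	hla_tag	haplotype_tag	DR3
rs9273363	6	32658525	A	T	0	hla_tag	haplotype_tag	DR15_DQ6
rs7454108	6	32693976	G	C	0	hla_tag	haplotype_tag	DR4_DQ8
rs12722051	6	32716648	C	T	0	hla_tag	haplotype_tag	DR13_DQ6
rs144530872	6	32722925	C	T	0	hla_tag	haplotype_tag	DR1_DQ5
rs9469200	6	32743847	A	C	0	hla_tag	haplotype_tag	DR9_DQ9
rs10947332	6	32750014	C	G	0	hla_tag	haplotype_tag	DR10_DQ5
rs34850435	6	32766017	G	A	0	hla_tag	haplotype_tag	DR14_DQ5
rs9268645	6	32792657	A	T	0	hla_tag	haplotype_tag	DR16_DQ5
rs9271366	6	32795611	T	G	0	hla_tag	haplotype_tag	DR12_DQ7
rs9235779	6	30048660	A	C	0.338	hla_other	linear	NA
rs9232917	6	30201703	A	T	0.332	hla_other	linear	NA
rs9254042	6	30799359	C	G	0.277	hla_other	linear	NA
rs9244980	6	30825728	G	A	0.343	hla_other	linear	NA
rs9247333	6	31027422	T	A	-0.139	hla_other	linear	NA
rs9210072	6	31146771	G	C	0.184	hla_other	linear	NA
rs9281640	6	31233136	G	A	0.201	hla_other	linear	NA
rs9268045	6	31294338	C	T	0.157	hla_other	linear	NA
rs9217494	6	31354861	A	T	-0.262	hla_other	linear	NA
rs9293639	6	31483745	T	A	0.408	hla_other	linear	NA
rs9212883	6	31566255	T	A	0.153	hla_other	linear	NA
rs9265624	6	31592633	T	G	0.105	hla_other	linear	NA
rs9257238	6	31927206	A	G	-0.236	hla_other	linear	NA
rs9270014	6	32046947	C	T	0.42	hla_other	linear	NA
rs9299786	6	32058122	C	T	-0.339	hla_other	linear	NA
rs9278094	6	32599237	A	C	0.256	hla_other	linear	NA
rs9277487	6	32675277	C	G	0.264	hla_other	linear	NA
rs9221912	6	32899321	A	T	-0.158	hla_other	linear	NA
rs9224084	6	32904760	G	A	0.435	hla_other	linear	NA
rs9267843	6	33005893	T	C	0.376	hla_other	linear	NA
rs9290420	6	33091033	T	C	-0.413	hla_other	linear	NA
rs689	11	2160994	C	A	0.34	non_hla	linear	NA
rs2476601	1	113834946	C	G	0.23	non_hla	linear	NA
rs6634240	14	143573062	T	A	0.074	non_hla	linear	NA
rs6673691	8	39157124	G	A	-0.088	non_hla	linear	NA
rs6622316	19	175822868	T	C	0.053	non_hla	linear	NA
rs6655359	21	78739123	A	T	-0.064	non_hla	linear	NA
rs6673564	22	67073940	G	T	0.226	non_hla	linear	NA
rs6665540	11	156340217	G	A	0.139	non_hla	linear	NA
rs6616219	18	114169356	C	T	0.056	non_hla	linear	NA
rs6610463	13	203884826	A	T	0.131	non_hla	linear	NA
rs6646931	17	138916497	A	T	-0.153	non_hla	linear	NA
rs6649587	10	222678467	T	C	0.232	non_hla	linear	NA
rs6683277	20	139075953	A	C	0.19	non_hla	linear	NA
rs6696948	4	37393459	T	A	0.18	non_hla	linear	NA
rs6613882	22	157683834	C	T	-0.231	non_hla	linear	NA
rs6619981	14	213464228	C	A	0.102	non_hla	linear	NA
rs6660731	17	168988531	G	T	-0.11	non_hla	linear	NA
rs6697898	19	113211224	G	T	0.127	non_hla	linear	NA
rs6680848	8	190938379	G	T	-0.15	non_hla	linear	NA
rs6611209	13	69390478	G	A	0.248	non_hla	linear	NA
rs6644748	1	234731252	G	C	0.074	non_hla	linear	NA
rs6625594	8	127267616	C	A	0.108	non_hla	linear	NA
rs6633158	19	188548939	C	A	0.104	non_hla	linear	NA
rs6648723	9	232297843	G	C	-0.237	non_hla	linear	NA
rs6683872	22	38459655	G	T	0.103	non_hla	linear	NA
rs6664736	22	163619708	T	G	-0.11	non_hla	linear	NA
rs6692000	10	162023119	A	G	0.212	non_hla	linear	NA
rs6615213	22	159147295	C	A	0.203	non_hla	linear	NA
rs6669522	4	132939647	C	A	0.052	non_hla	linear	NA
rs6650328	19	203950293	A	C	-0.201	non_hla	linear	NA
rs6661552	21	198134738	G	C	-0.189	non_hla	linear	NA
rs6632806	19	74001397	T	A	0.07	non_hla	linear	NA
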