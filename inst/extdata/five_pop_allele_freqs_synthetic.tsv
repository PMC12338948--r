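variant_id	uganda	cameroon	us_african	us_european	us_hispanic
rs17426593	0.142	0.147	0.1546	0.2045	0.1826
rs28746898	0.6344	0.625	0.6109	0.5277	0.5624
rs7775228	0.3904	0.3999	0.4144	0.4986	0.4636
rs1281934	0.3381	0.3292	0.3161	0.2475	0.2745
rs2187668	0.4744	0.4844	0.4994	0.5836	0.5492
rs9273363	0.4825	0.4725	0.4576	0.3752	0.4085
rs7454108	0.3586	0.3679	0.3819	0.4647	0.4301
rs12722051	0.6636	0.6547	0.641	0.5596	0.5938
rs144530872	0.3087	0.3173	0.3305	0.4095	0.3761
rs9469200	0.2178	0.2247	0.2353	0.3018	0.2732
rs10947332	0.2347	0.2347	0.2347	0.2347	0.2347
rs34850435	0.4694	0.4694	0.4694	0.4694	0.4694
rs9268645	0.3267	0.3267	0.3267	0.3267	0.3267
rs9271366	0.4048	0.4048	0.4048	0.4048	0.4048
rs9235779	0.2688	0.2767	0.2889	0.3634	0.3316
rs9232917	0.1871	0.1932	0.2028	0.2633	0.237
rs9254042	0.3608	0.3701	0.3842	0.4671	0.4325
rs9244980	0.4938	0.5038	0.5188	0.6023	0.5684
rs9247333	0.5698	0.56	0.5451	0.4603	0.4952
rs9210072	0.3803	0.3897	0.4041	0.4879	0.453
rs9281640	0.3393	0.3483	0.362	0.4436	0.4094
rs9268045	0.425	0.4348	0.4496	0.5344	0.4994
rs9217494	0.4804	0.4704	0.4555	0.3732	0.4065
rs9293639	0.5229	0.5329	0.5478	0.6299	0.5967
rs9212883	0.4283	0.4381	0.4529	0.5377	0.5028
rs9265624	0.2459	0.2534	0.2649	0.3361	0.3056
rs9257238	0.3698	0.3605	0.3468	0.2743	0.303
rs9270014	0.4354	0.4452	0.4601	0.5449	0.51
rs9299786	0.5774	0.5677	0.5529	0.4681	0.5031
rs9278094	0.4954	0.5054	0.5204	0.6038	0.5699
rs9277487	0.3703	0.3797	0.3939	0.4773	0.4426
rs9221912	0.6412	0.632	0.6179	0.5351	0.5697
rs9224084	0.2289	0.236	0.247	0.3155	0.2861
rs9267843	0.309	0.3176	0.3308	0.4098	0.3764
rs9290420	0.5801	0.5703	0.5556	0.4708	0.5058
rs689	0.1166	0.1208	0.1273	0.1701	0.1513
rs2476601	0.271	0.279	0.2912	0.366	0.3341
rs6634240	0.215	0.2218	0.2323	0.2983	0.2699
rs6673691	0.6561	0.647	0.6332	0.5513	0.5856
rs6622316	0.2482	0.2558	0.2674	0.3389	0.3083
rs6655359	0.5282	0.5182	0.5032	0.4189	0.4533
rs6673564	0.1882	0.1944	0.204	0.2647	0.2384
rs6665540	0.3512	0.3604	0.3743	0.4567	0.4222
rs6616219	0.4497	0.4596	0.4745	0.5592	0.5245
rs6610463	0.1627	0.1682	0.1768	0.2318	0.2078
rs6646931	0.5877	0.578	0.5633	0.4787	0.5136
rs6649587	0.4643	0.4743	0.4893	0.5737	0.5392
rs6683277	0.5211	0.5311	0.546	0.6282	0.5949
rs6696948	0.2824	0.2906	0.3031	0.3793	0.3469
rs6613882	0.4565	0.4466	0.4318	0.351	0.3836
rs6619981	0.5044	0.5144	0.5294	0.6124	0.5787
rs6660731	0.3871	0.3777	0.3637	0.2892	0.3188
rs6697898	0.2293	0.2365	0.2475	0.316	0.2866
rs6680848	0.6154	0.6059	0.5915	0.5075	0.5424
rs6611209	0.1733	0.1791	0.1881	0.2455	0.2205
rs6644748	0.3871	0.3966	0.4111	0.4951	0.4602
rs6625594	0.1499	0.1551	0.1631	0.215	0.1923
rs6633158	0.4428	0.4527	0.4676	0.5523	0.5175
rs6648723	0.4503	0.4404	0.4257	0.3454	0.3777
rs6683872	0.2425	0.2499	0.2613	0.332	0.3017
rs6664736	0.5112	0.5012	0.4862	0.4025	0.4366
rs6692000	0.4082	0.4179	0.4325	0.5171	0.4821
rs6615213	0.5196	0.5295	0.5445	0.6267	0.5935
rs6669522	0.1354	0.1402	0.1476	0.1956	0.1745
rs6650328	0.3683	0.359	0.3453	0.2729	0.3016
rs6661552	0.6406	0.6314	0.6173	0.5345	0.5691
rs6632806	0.4153	0.425	0.4397	0.5244	0.4894
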