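sentinel	ld_block_bp	n_snps_ld	dataset	proxy	proxy_allele	proxy_maf	r2
rs61816761	988882	20	other	rs61816766	C	0.02	0.50
rs61816761	988882	20	ub_biopsy	rs61816764	T	0.05	0.21
rs7523907	41739	56	other	rs3108155	G	0.39	0.83
rs7523907	41739	56	ub_biopsy	rs2056625	A	0.36	0.73
rs12479210	458394	578	ub_biopsy	rs2270298	G	0.25	0.47
rs12479210	458394	578	ub_brush	rs2241116	A	0.20	0.46
rs34290285	69955	157	ub_biopsy	rs34077392	C	0.37	0.43
rs560026225	622215	150	other	rs72687036	G	0.24	0.66
rs1837253	71462	29	none				
rs1438673	227233	353	ub_biopsy	rs2289277	G	0.46	0.73
rs1438673	227233	353	ub_nasal	rs7524421	G	0.24	1.00
rs3749833	526932	325	ub_nasal	rs11748326	T	0.23	0.76
rs1986009	365939	239	other	rs12652920	C	0.19	1.00
rs1986009	365939	239	ub_biopsy	rs12652920	C	0.19	1.00
rs1986009	365939	239	ub_brush	rs4705952	G	0.27	0.21
rs9273410	554975	5739	none				
rs776111176	574227	1447	other	rs3997872	A	0.16	0.82
rs367983479	244383	191	other	rs1504215	A	0.36	0.85
rs367983479	244383	191	ub_biopsy	rs4142967	T	0.46	0.56
rs71266076	175000	206	other	rs7824993	A	0.35	0.81
rs144829310	496605	234	ub_biopsy	rs1929996	C	0.31	0.43
rs10905284	67858	96	none				
rs11603634	146648	187	ub_biopsy	rs11602802	C	0.33	0.40
rs7936312	316410	277	other	rs7936323	A	0.47	0.96
rs7305461	315101	120	other	rs1131017	C	0.41	0.75
rs703816	284371	165	ub_biopsy	rs167769	T	0.33	0.82
rs10519068	108343	123	ub_biopsy	rs2279292	C	0.15	0.91
rs10519068	108343	123	ub_brush	rs2279296	G	0.45	0.13
rs10519068	108343	123	ub_nasal	rs2279296	G	0.45	0.13
rs72743461	30796	45	ub_brush	rs10152544	C	0.48	0.30
rs72743461	30796	45	ub_nasal	rs10152544	C	0.48	0.30
rs7203459	429719	435	ub_biopsy	rs12919828	G	0.25	0.98
rs7203459	429719	435	ub_brush	rs6498135	A	0.40	0.30
rs2941522	805248	896	ub_biopsy	rs907091	T	0.49	0.96
rs112502960	270023	370	other	rs62076439	T	0.36	1.00
rs61840192	201710	249	other	rs1031163	T	0.42	1.00
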