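block	tf	cg	total_tf_genes	tf_genes_in_set	p_count	p_score
mated_plus_vs_minus	prd	CG6716	5546	77	0	0
mated_plus_vs_minus	exex	CG8254	4109	57	0	0.000013
mated_vs_virgin_down	psq	CG2368	4128	28	0.000061	0.000001
mated_vs_virgin_down	Sin3A	CG8815	3025	31	0	0.000002
mated_vs_virgin_down	Stat92E	CG4257	9349	43	0.002365	0.000002
mated_vs_virgin_down	YL-1	CG4621	4548	38	0	0.000004
mated_vs_virgin_down	gfzf	CG33546	3981	34	0	0.000008
mated_vs_virgin_down	Sry-delta	CG17958	4632	34	0.000006	0.00001
mated_vs_virgin_down	M1BP	CG9797	3749	38	0	0.000017
mated_vs_virgin_down	HmgD	CG17950	2478	26	0	0.000021
mated_vs_virgin_down	CG4617	CG4617	4508	33	0.000019	0.000024
mated_vs_virgin_down	Crg-1	CG32788	2862	28	0.000001	0.000034
mated_vs_virgin_down	Dif	CG6794	2629	22	0.00005	0.000042
mated_vs_virgin_down	Clamp	CG1832	1980	18	0.000044	0.000054
mated_vs_virgin_down	CG1620	CG1620	3122	29	0	0.000058
mated_vs_virgin_down	ovo	CG6824	3098	26	0.000015	0.000067
mated_vs_virgin_up	exex	CG8254	4109	311	0	0
mated_vs_virgin_up	prd	CG6716	5546	373	0	0
mated_vs_virgin_up	grn	CG9656	3627	234	0.000005	0.000015
virgin_plus_vs_minus	prd	CG6716	5546	21	0.007	0.012
virgin_plus_vs_minus	exex	CG8254	4109	18	0.014	0.07
virgin_plus_vs_minus	cic	CG43122	3909	14	0.16	0.447
virgin_plus_vs_minus	cnc	CG43286	695	3	0.278	0.316
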