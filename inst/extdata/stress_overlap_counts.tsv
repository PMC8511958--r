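label	total	n_a	n_b	overlap
virgin_landis_aging	13964	45	1470	15
virgin_landis_o2	13964	45	897	12
virgin_landis_h2o2	13964	45	1641	11
virgin_landis_heat	13964	45	1566	16
virgin_landis_ir907	13964	45	1388	9
virgin_moskalev_cold	13964	45	869	10
virgin_moskalev_ir144	13964	45	195	3
virgin_moskalev_starvation	13964	45	79	2
virgin_dobson_dr	13964	45	442	17
virgin_dobson_rapa	13964	45	350	14
virgin_gershman_yeast	13964	45	631	4
virgin_mack_mating	13964	45	545	3
virgin_wang_tubule	13964	45	1315	5
virgin_kingjones_pb	13964	45	828	17
virgin_kingjones_pb_dhr96	13964	45	503	9
virgin_zimmerman_sleep	13964	45	44	4
virgin_deng_rox	13964	45	3464	20
mated_landis_aging	13964	100	1470	27
mated_landis_o2	13964	100	897	27
mated_landis_h2o2	13964	100	1641	29
mated_landis_heat	13964	100	1566	31
mated_landis_ir907	13964	100	1388	21
mated_moskalev_cold	13964	100	869	34
mated_moskalev_ir144	13964	100	195	9
mated_moskalev_starvation	13964	100	79	1
mated_dobson_dr	13964	100	442	39
mated_dobson_rapa	13964	100	350	34
mated_gershman_yeast	13964	100	631	7
mated_mack_mating	13964	100	545	2
mated_wang_tubule	13964	100	1315	15
mated_kingjones_pb	13964	100	828	35
mated_kingjones_pb_dhr96	13964	100	503	17
mated_zimmerman_sleep	13964	100	44	4
mated_deng_rox	13964	100	3464	42
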