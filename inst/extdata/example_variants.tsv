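patient_id	sample_id	chrom	pos	ref	alt	mt_alt	mt_total	called	context	mutation_class
P25	P25_P	chr15	77310812	A	C	72	1160	TRUE	CAT	metspec_driver
P25	P25_P	chr11	68080126	C	T	25	1243	TRUE	ACG	metspec_driver
P25	P25_P	chr17	39723335	G	T	0	2104	FALSE	AGC	metspec_driver
P25	P25_P	chr3	178936091	G	A	610	1385	TRUE	AGA	truncal
P25	P25_P	chr2	29443610	C	A	14	980	TRUE	GCT	NA
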