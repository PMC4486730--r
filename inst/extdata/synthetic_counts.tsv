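animal_id	replicate	role	cpm_ml	sample_id	aliquot_ml	diluent_ml	background_cpm_ml
seal_01	1	equilibrium	491.632	seal_01	NA	NA	NA
seal_01	2	equilibrium	500.0304	seal_01	NA	NA	NA
seal_01	3	equilibrium	487.7701	seal_01	NA	NA	NA
seal_01	1	background	29.8996	seal_01	NA	NA	NA
seal_01	2	background	28.881	seal_01	NA	NA	NA
seal_01	3	background	29.9277	seal_01	NA	NA	NA
seal_02	1	equilibrium	482.2821	seal_02	NA	NA	NA
seal_02	2	equilibrium	485.7377	seal_02	NA	NA	NA
seal_02	3	equilibrium	464.0878	seal_02	NA	NA	NA
seal_02	1	background	29.7749	seal_02	NA	NA	NA
seal_02	2	background	29.4407	seal_02	NA	NA	NA
seal_02	3	background	30.0199	seal_02	NA	NA	NA
NA	1	standard	230.5597	std_01	0.01	1000	30
NA	2	standard	241.8647	std_01	0.01	1000	30
NA	3	standard	228.7583	std_01	0.01	1000	30
NA	1	standard	225.9118	std_02	0.01	1000	30
NA	2	standard	232.1104	std_02	0.01	1000	30
NA	3	standard	230.5287	std_02	0.01	1000	30
NA	1	standard	228.9337	std_03	0.01	1000	30
NA	2	standard	233.6427	std_03	0.01	1000	30
NA	3	standard	234.2694	std_03	0.01	1000	30
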