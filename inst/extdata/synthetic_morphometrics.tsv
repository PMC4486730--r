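animal_id	replicate	site	girth_cm	height_cm	width_cm	curvilinear_cm	us_dorsal_cm	us_lateral_cm	total_length_cm	mass_kg
seal_01	1	ankles	62.728	18.459	21.575	18.237	NA	NA	273.247	403.114
seal_01	1	pelvis	135.695	39.888	46.029	52.77	7.506	7.849	273.247	403.114
seal_01	1	umbilicus	172.605	50.263	59.591	88.024	9.666	6.961	273.247	403.114
seal_01	1	mid	185.858	53.603	62.975	117.505	8.617	7.782	273.247	403.114
seal_01	1	sternum	179.664	52.714	61.918	148.108	8.586	7.019	273.247	403.114
seal_01	1	axilla	161.546	45.267	56.354	178.288	8.454	7.171	273.247	403.114
seal_01	1	neck	123.198	35.882	41.866	207.128	6.332	6.208	273.247	403.114
seal_01	1	ears	65.921	19.903	21.268	237.561	NA	NA	273.247	403.114
seal_01	2	ankles	61.802	18.565	22.193	17.415	NA	NA	275.73	403.114
seal_01	2	pelvis	134.333	40.587	45.656	52.362	8.243	8.121	275.73	403.114
seal_01	2	umbilicus	172.925	49.786	60.074	86.52	8.711	7.984	275.73	403.114
seal_01	2	mid	186.149	53.87	63.971	117.926	8.113	7.829	275.73	403.114
seal_01	2	sternum	178.298	51.294	61.963	146.363	8.744	7.183	275.73	403.114
seal_01	2	axilla	161.206	45.679	56.755	177.929	8.003	7.119	275.73	403.114
seal_01	2	neck	121.862	36.056	42.81	206.182	7.59	5.722	275.73	403.114
seal_01	2	ears	66.143	20.211	22.577	239.134	NA	NA	275.73	403.114
seal_01	3	ankles	63.387	18.044	22.384	15.474	NA	NA	274.386	403.114
seal_01	3	pelvis	134.601	38.908	45.614	53.647	8.626	7.331	274.386	403.114
seal_01	3	umbilicus	173.359	49.767	59.685	87.992	8.923	7.575	274.386	403.114
seal_01	3	mid	185.213	54.843	63.585	116.853	8.172	7.839	274.386	403.114
seal_01	3	sternum	181.122	51.716	61.704	146.887	8.999	6.891	274.386	403.114
seal_01	3	axilla	161.545	45.977	56.491	177.491	7.173	7.092	274.386	403.114
seal_01	3	neck	123.301	35.922	41.669	207.897	7.791	6.246	274.386	403.114
seal_01	3	ears	65.826	20.801	21.614	236.037	NA	NA	274.386	403.114
seal_02	1	ankles	63.133	18.275	21.213	17.136	NA	NA	274.331	397.481
seal_02	1	pelvis	135.881	40.952	46.877	53.995	8.421	7.522	274.331	397.481
seal_02	1	umbilicus	172.062	50.722	59.161	87.64	9.671	7.575	274.331	397.481
seal_02	1	mid	187.274	54.058	64.266	117.797	10.219	7.87	274.331	397.481
seal_02	1	sternum	180.406	51.686	62.376	148.733	9.423	7.684	274.331	397.481
seal_02	1	axilla	161.567	45.365	55.895	179.802	7.828	6.593	274.331	397.481
seal_02	1	neck	123.42	35.886	41.34	207.597	7.014	7.071	274.331	397.481
seal_02	1	ears	66.214	19.87	21.509	237.218	NA	NA	274.331	397.481
seal_02	2	ankles	62.536	18.794	22.41	17.498	NA	NA	272.119	397.481
seal_02	2	pelvis	136.368	39.707	45.9	55.357	7.657	7.28	272.119	397.481
seal_02	2	umbilicus	174.011	50.016	59.609	89.563	8.857	7.386	272.119	397.481
seal_02	2	mid	184.702	53.661	64.027	116.057	9.473	7.754	272.119	397.481
seal_02	2	sternum	179.347	51.715	62.285	147.489	8.343	7.003	272.119	397.481
seal_02	2	axilla	160	46.113	55.768	177.65	7.173	7.63	272.119	397.481
seal_02	2	neck	123.129	36.905	42.176	206.015	6.997	5.984	272.119	397.481
seal_02	2	ears	65.681	20.971	21.721	237.328	NA	NA	272.119	397.481
seal_02	3	ankles	63.031	17.866	21.414	17.236	NA	NA	275.092	397.481
seal_02	3	pelvis	135.663	40.497	46.495	52.207	8.381	7.37	275.092	397.481
seal_02	3	umbilicus	174.441	50.459	59.029	87.281	8.557	7.875	275.092	397.481
seal_02	3	mid	184.544	53.962	63.709	117.222	10.139	7.997	275.092	397.481
seal_02	3	sternum	177.387	51.612	62.286	148.211	8.296	7.439	275.092	397.481
seal_02	3	axilla	160.808	45.952	56.761	178.136	8.61	7.557	275.092	397.481
seal_02	3	neck	122.567	36.276	42.287	205.573	6.696	6.275	275.092	397.481
seal_02	3	ears	66.033	20.096	22.323	235.396	NA	NA	275.092	397.481
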