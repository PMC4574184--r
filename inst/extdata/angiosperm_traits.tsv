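species	recomb_rate_cM_Mb	euchromatin_rate_cM_Mb	genome_size_Mb	ltr_proportion	copia_proportion	gypsy_proportion	gene_density_per_Mb	avg_gene_family_size
Arabidopsis_lyrata	2.26	2.87	207.0	0.200	NA	NA	157.83	0.768
Arabidopsis_thaliana	4.17	4.27	125.0	0.040	NA	NA	248.91	1.209
Brachypodium_distachyon	5.52	NA	272.0	0.214	0.049	0.161	93.87	0.952
Brassica_rapa	4.83	5.10	283.8	0.271	NA	NA	144.99	0.790
Capsella_rubella	4.15	NA	134.8	0.094	NA	NA	196.74	0.751
Carica_papaya	2.82	3.22	372.0	0.333	0.055	0.278	66.52	0.712
Citrus_clementina	2.77	3.31	301.4	0.199	0.079	0.120	81.40	0.787
Citrus_sinensis	2.19	2.62	320.5	0.153	0.071	0.082	91.87	0.784
Cucumis_sativus	3.15	3.41	243.5	0.104	0.054	0.038	109.58	0.749
Eucalyptus_grandis	2.09	NA	691.0	0.219	NA	NA	52.64	0.790
Fragaria_vesca	1.86	NA	240.0	0.160	NA	NA	104.38	1.924
Glycine_max	2.40	3.38	1060.0	0.430	0.130	0.300	43.80	0.867
Gossypium_raimondii	1.96	3.97	761.4	0.449	0.338	0.111	53.82	0.821
Linum_usitatissimum	3.42	NA	318.3	0.184	NA	NA	136.30	0.823
Malus_domestica	1.52	NA	742.3	0.307	0.055	0.252	77.31	0.845
Manihot_esculenta	1.91	3.03	760.0	0.111	NA	NA	40.35	0.811
Medicago_truncatula	3.00	3.35	257.6	0.242	0.410	0.057	171.33	0.708
Mimulus_guttatus	4.96	NA	321.7	0.200	0.100	0.100	87.47	0.790
Oryza_sativa	4.73	5.41	372.0	0.235	0.025	0.120	114.66	1.084
Panicum_virgatum	1.11	NA	1358.0	NA	NA	NA	72.17	0.805
Phaseolus_vulgaris	2.67	2.78	521.1	0.367	0.094	0.251	52.19	0.794
Populus_trichocarpa	4.96	6.73	485.0	0.065	0.016	0.049	94.13	1.431
Prunus_persica	2.45	2.54	227.3	0.186	0.086	0.100	122.53	0.813
Setaria_italica	3.28	NA	405.7	0.250	NA	NA	87.43	0.736
Solanum_lycopersicum	1.81	7.50	760.0	0.618	0.063	0.197	45.69	2.156
Solanum_tuberosum	1.15	1.63	727.0	0.522	0.038	0.152	48.15	1.232
Sorghum_bicolor	2.12	4.02	738.5	0.544	0.052	0.190	37.43	1.464
Theobroma_cacao	2.69	NA	326.9	0.160	0.070	0.090	88.09	1.537
Vitis_vinifera	2.99	NA	487.1	0.145	0.084	0.032	68.80	0.760
Zea_mays	0.72	1.24	2066.4	0.751	0.218	0.377	15.75	0.738
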