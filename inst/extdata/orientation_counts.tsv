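family	tissue	compartment	n	co	counter	co_pct	counter_pct
L1Hs	cerebellum	genic	842	345	497	40.97	59.03
L1Hs	frontal_cortex	genic	236	97	139	41.10	58.90
L1Hs	SVZ	genic	584	239	345	40.92	59.08
L1Hs	dentate_gyrus	genic	1558	644	914	41.34	58.66
L1Hs	myocardium	genic	578	234	344	40.48	59.52
L1Hs	cerebellum	promoter	92	38	54	41.30	58.70
L1Hs	frontal_cortex	promoter	31	20	11	64.52	35.48
L1Hs	SVZ	promoter	74	31	43	41.89	58.11
L1Hs	dentate_gyrus	promoter	177	88	89	49.72	50.28
L1Hs	myocardium	promoter	62	34	28	54.84	45.16
AluYa5	cerebellum	genic	623	323	301	51.85	48.15
AluYa5	frontal_cortex	genic	1028	497	531	48.35	51.65
AluYa5	SVZ	genic	609	304	305	49.92	50.08
AluYa5	dentate_gyrus	genic	1465	691	774	47.17	52.83
AluYa5	myocardium	genic	589	279	310	47.37	52.63
AluYa5	cerebellum	promoter	67	29	38	43.28	56.72
AluYa5	frontal_cortex	promoter	105	43	62	40.95	59.05
AluYa5	SVZ	promoter	61	32	29	52.46	47.54
AluYa5	dentate_gyrus	promoter	105	45	60	42.86	57.14
AluYa5	myocardium	promoter	55	25	30	45.45	54.55
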