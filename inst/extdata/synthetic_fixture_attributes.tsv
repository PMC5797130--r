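word	aoa_mean	aoa_sd	frequency	polysemy	concreteness	reaction_time	length
w01	2	0.21	5000	10	5	503	3
w02	2.15	0.22	2500	10	4.93220338983051	506	3
w03	2.3	0.23	1667	10	4.86440677966102	509	3
w04	2.45	0.24	1250	10	4.79661016949153	512	3
w05	2.6	0.25	1000	10	4.72881355932203	515	3
w06	2.75	0.26	833	10	4.66101694915254	518	3
w07	2.9	0.27	714	9	4.59322033898305	521	3
w08	3.05	0.28	625	9	4.52542372881356	524	3
w09	3.2	0.29	556	9	4.45762711864407	527	3
w10	3.35	0.3	500	9	4.38983050847458	530	3
w11	4	0.31	455	9	4.32203389830508	533	3
w12	4.08	0.32	417	9	4.25423728813559	536	4
w13	4.16	0.33	385	8	4.1864406779661	539	4
w14	4.24	0.34	357	8	4.11864406779661	542	4
w15	4.32	0.35	333	8	4.05084745762712	545	4
w16	4.4	0.36	312	8	3.98305084745763	548	4
w17	4.48	0.37	294	8	3.91525423728814	551	4
w18	4.56	0.38	278	8	3.84745762711864	554	4
w19	4.64	0.39	263	7	3.77966101694915	557	4
w20	4.72	0.4	250	7	3.71186440677966	560	4
w21	4.8	0.41	238	7	3.64406779661017	563	4
w22	4.88	0.42	227	7	3.57627118644068	566	4
w23	4.96	0.43	217	7	3.50847457627119	569	4
w24	5.04	0.44	208	7	3.4406779661017	572	5
w25	5.12	0.45	200	6	3.3728813559322	575	5
w26	5.2	0.46	192	6	3.30508474576271	578	5
w27	5.28	0.47	185	6	3.23728813559322	581	5
w28	5.36	0.48	179	6	3.16949152542373	584	5
w29	5.44	0.49	172	6	3.10169491525424	587	5
w30	5.52	0.5	167	6	3.03389830508475	590	5
w31	5.6	0.51	161	5	2.96610169491525	593	5
w32	5.68	0.52	156	5	2.89830508474576	596	5
w33	5.76	0.53	152	5	2.83050847457627	599	5
w34	5.84	0.54	147	5	2.76271186440678	602	5
w35	5.92	0.55	143	5	2.69491525423729	605	5
w36	6	0.56	139	5	2.6271186440678	608	6
w37	6.08	0.57	135	4	2.55932203389831	611	6
w38	6.16	0.58	132	4	2.49152542372881	614	6
w39	6.24	0.59	128	4	2.42372881355932	617	6
w40	6.32	0.6	125	4	2.35593220338983	620	6
w41	6.4	0.61	122	4	2.28813559322034	623	6
w42	6.48	0.62	119	4	2.22033898305085	626	6
w43	6.56	0.63	116	3	2.15254237288136	629	6
w44	6.64	0.64	114	3	2.08474576271186	632	6
w45	6.72	0.65	111	3	2.01694915254237	635	6
w46	6.8	0.66	109	3	1.94915254237288	638	6
w47	6.88	0.67	106	3	1.88135593220339	641	6
w48	6.96	0.68	104	3	1.8135593220339	644	7
w49	7.04	0.69	102	2	1.74576271186441	647	7
w50	7.12	0.7	100	2	1.67796610169492	650	7
w51	7.2	0.71	98	2	1.61016949152542	653	7
w52	7.28	0.72	96	2	1.54237288135593	656	7
w53	7.36	0.73	94	2	1.47457627118644	659	7
w54	7.44	0.74	93	2	1.40677966101695	662	7
w55	7.52	0.75	91	1	1.33898305084746	665	7
w56	7.6	0.76	89	1	1.27118644067797	668	7
w57	7.68	0.77	88	1	1.20338983050847	671	7
w58	7.76	0.78	86	1	1.13559322033898	674	7
w59	7.84	0.79	85	1	1.06779661016949	677	7
w60	7.92	0.8	83	1	1	680	8
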