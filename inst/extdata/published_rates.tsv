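table	genotype	background	reporter	absolute	ci_low	ci_high	relative	absolute_is_bound
1	E35	E35	CAN1	27	23	49	1	FALSE
1	E35	E35	his7-2	0.6	0.4	1.0	1	FALSE
1	E35 hst3 hst4	E35	CAN1	690	470	850	25	FALSE
1	E35 hst3 hst4	E35	his7-2	16	8	32	27	FALSE
1	BY4742	BY4742	CAN1	17	14	25	1	FALSE
1	BY4742 hst3 hst4	BY4742	CAN1	500	390	600	28	FALSE
1	E134	E134	CAN1	19	16	24	1	FALSE
1	E134	E134	his7-2	0.6	0.6	1.0	1	FALSE
1	hst3	E134	CAN1	33	25	42	2	FALSE
1	hst3	E134	his7-2	1.2	0.9	1.5	2	FALSE
1	hst4	E134	CAN1	25	14	41	1	FALSE
1	hst4	E134	his7-2	1.0	0.5	1.6	2	FALSE
1	hst3 hst4	E134	CAN1	480	420	570	25	FALSE
1	hst3 hst4	E134	his7-2	14	11	23	23	FALSE
1	rtt109	E134	CAN1	37	29	51	2	FALSE
1	rtt109	E134	his7-2	5.1	2.6	7.4	9	FALSE
1	hst3 hst4 rtt109	E134	CAN1	30	19	33	2	FALSE
1	hst3 hst4 rtt109	E134	his7-2	3.1	2.2	5.2	5	FALSE
1	H3K56R	E134	CAN1	39	29	56	2	FALSE
1	H3K56R	E134	his7-2	5.7	3.4	9.4	10	FALSE
1	hst3 hst4 H3K56R	E134	CAN1	32	28	55	2	FALSE
1	hst3 hst4 H3K56R	E134	his7-2	7.0	3.3	9.6	12	FALSE
1	H3K56Q	E134	CAN1	84	59	160	4	FALSE
1	H3K56Q	E134	his7-2	5.8	4.3	9	10	FALSE
1	hst3 hst4 H3K56Q	E134	CAN1	120	83	150	6	FALSE
1	hst3 hst4 H3K56Q	E134	his7-2	5.0	3.8	7.3	8	FALSE
1	hst3 H3K56Q	E134	CAN1	85	76	140	5	FALSE
1	hst3 H3K56Q	E134	his7-2	5.6	3.9	10	9	FALSE
1	hst1 H3K56Q	E134	CAN1	96	77	130	5	FALSE
1	hst1 H3K56Q	E134	his7-2	9.3	5.9	15	16	FALSE
1	hst1	E134	CAN1	19	16	28	1	FALSE
1	hst1	E134	his7-2	0.6	0.6	0.9	1	TRUE
1	hst2	E134	CAN1	25	16	32	1	FALSE
1	hst2	E134	his7-2	0.7	0.4	1.2	1	FALSE
1	hst1 hst3	E134	CAN1	19	10	25	1	FALSE
1	hst1 hst3	E134	his7-2	1.4	0.6	2.2	2	FALSE
1	hst1 hst2 hst3	E134	CAN1	19	15	29	1	FALSE
1	hst1 hst2 hst3	E134	his7-2	0.5	0.4	0.7	1	FALSE
1	hst1 hst2 hst4	E134	CAN1	15	11	24	1	FALSE
1	hst1 hst2 hst4	E134	his7-2	0.8	0.6	1.0	1	FALSE
1	hst3 hst4 hst1	E134	CAN1	1100	960	1500	58	FALSE
1	hst3 hst4 hst1	E134	his7-2	31	29	38	52	FALSE
1	hst3 hst4 hst1 hst2	E134	CAN1	1600	1100	1900	86	FALSE
1	hst3 hst4 hst1 hst2	E134	his7-2	35	28	53	58	FALSE
1	hst3 hst4 hst2	E134	CAN1	680	440	960	36	FALSE
1	hst3 hst4 hst2	E134	his7-2	18	11	32	30	FALSE
2	E134	E134	CAN1	19	16	24	1	FALSE
2	E134	E134	his7-2	0.6	0.6	1.0	1	FALSE
2	rtt109	E134	CAN1	37	29	51	2	FALSE
2	rtt109	E134	his7-2	5.1	2.6	7.4	9	FALSE
2	H3K56R	E134	CAN1	39	29	56	2	FALSE
2	H3K56R	E134	his7-2	5.7	3.4	9.4	10	FALSE
2	asf1	E134	CAN1	35	26	49	2	FALSE
2	asf1	E134	his7-2	8.5	6.3	10.2	14	FALSE
2	rtt109 H3K56R	E134	CAN1	44	34	67	2	FALSE
2	rtt109 H3K56R	E134	his7-2	6.7	3.6	11.7	11	FALSE
2	htz1	E134	CAN1	18	12	32	1	FALSE
2	htz1	E134	his7-2	0.8	0.7	1.7	1	FALSE
2	swr1	E134	CAN1	16	12	24	1	FALSE
2	swr1	E134	his7-2	0.7	0.5	2.2	1	FALSE
2	msh2	E134	CAN1	620	450	830	33	FALSE
2	msh2	E134	his7-2	140	110	170	230	FALSE
2	msh2 rtt109	E134	CAN1	1600	1000	2200	84	FALSE
2	msh2 rtt109	E134	his7-2	230	170	290	390	FALSE
2	msh2 H3K56R	E134	CAN1	1600	1000	2400	83	FALSE
2	msh2 H3K56R	E134	his7-2	510	350	610	840	FALSE
2	msh2 asf1	E134	CAN1	1900	1300	3700	100	FALSE
2	msh2 asf1	E134	his7-2	590	430	920	990	FALSE
2	pol2-4	E134	CAN1	75	56	100	4	FALSE
2	pol2-4	E134	his7-2	3.9	3.5	5	7	FALSE
2	pol2-4 rtt109	E134	CAN1	170	110	280	9	FALSE
2	pol2-4 rtt109	E134	his7-2	16	9	24	27	FALSE
2	pol2-4 H3K56R	E134	CAN1	370	240	520	20	FALSE
2	pol2-4 H3K56R	E134	his7-2	39	31	56	65	FALSE
2	pol2-4 asf1	E134	CAN1	300	260	530	15	FALSE
2	pol2-4 asf1	E134	his7-2	19	17	27	32	FALSE
2	pol3-5DV	E134	CAN1	150	130	190	7	FALSE
2	pol3-5DV	E134	his7-2	9.7	8	16	16	FALSE
2	pol3-5DV rtt109	E134	CAN1	280	200	430	15	FALSE
2	pol3-5DV rtt109	E134	his7-2	20	15	24	33	FALSE
2	pol3-5DV H3K56R	E134	CAN1	600	470	920	32	FALSE
2	pol3-5DV H3K56R	E134	his7-2	38	23	48	63	FALSE
2	pol3-5DV asf1	E134	CAN1	620	330	800	32	FALSE
2	pol3-5DV asf1	E134	his7-2	34	24	42	57	FALSE
3	E134	E134	CAN1	19	16	24	1	FALSE
3	E134	E134	his7-2	0.6	0.6	1.0	1	FALSE
3	hst3 hst4	E134	CAN1	480	420	570	25	FALSE
3	hst3 hst4	E134	his7-2	14	11	23	23	FALSE
3	rev3	E134	CAN1	11	8	17	0.6	FALSE
3	rev3	E134	his7-2	0.6	0.6	0.7	1	FALSE
3	rev3 hst3 hst4	E134	CAN1	500	420	830	26	FALSE
3	rev3 hst3 hst4	E134	his7-2	17	14	20	28	FALSE
3	rtt101	E134	CAN1	36	25	71	2	FALSE
3	rtt101	E134	his7-2	3.4	2	7.8	6	FALSE
3	rtt101 hst3 hst4	E134	CAN1	41	36	60	2	FALSE
3	rtt101 hst3 hst4	E134	his7-2	2.3	1.9	7.3	4	FALSE
3	ctf18	E134	CAN1	25	19	37	1	FALSE
3	ctf18	E134	his7-2	1.7	0.8	2.8	3	FALSE
3	ctf18 hst3 hst4	E134	CAN1	120	100	180	6	FALSE
3	ctf18 hst3 hst4	E134	his7-2	4.6	2.6	9.2	8	FALSE
3	rtt109	E134	CAN1	37	29	51	2	FALSE
3	rtt109	E134	his7-2	5.1	2.6	7.4	9	FALSE
3	rev3 rtt109	E134	CAN1	18	16	22	1	FALSE
3	rev3 rtt109	E134	his7-2	2.6	1.6	3.1	4	FALSE
3	rad51	E134	CAN1	370	290	520	19	FALSE
3	rad51	E134	his7-2	4.6	3.7	5.9	8	FALSE
3	rad51 rtt109	E134	CAN1	410	250	430	22	FALSE
3	rad51 rtt109	E134	his7-2	4.4	2.8	8.3	8	FALSE
3	rad52	E134	CAN1	390	310	480	21	FALSE
3	rad52	E134	his7-2	4.0	3.2	5.7	7	FALSE
3	rad52 rtt109	E134	CAN1	390	280	680	21	FALSE
3	rad52 rtt109	E134	his7-2	5.5	1.6	8.1	9	FALSE
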