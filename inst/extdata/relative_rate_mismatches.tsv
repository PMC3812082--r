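table	genotype	reporter	printed	computed
1	E35 hst3 hst4	CAN1	25	26
1	BY4742 hst3 hst4	CAN1	28	29
1	hst3 H3K56Q	CAN1	5	4
1	hst3 hst4 hst1 hst2	CAN1	86	84
2	msh2 H3K56R	CAN1	83	84
2	msh2 rtt109	his7-2	390	380
2	msh2 H3K56R	his7-2	840	850
2	msh2 asf1	his7-2	990	980
2	pol2-4 H3K56R	CAN1	20	19
2	pol2-4 asf1	CAN1	15	16
2	pol3-5DV	CAN1	7	8
2	pol3-5DV asf1	CAN1	32	33
3	rad51 rtt109	his7-2	8	7
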