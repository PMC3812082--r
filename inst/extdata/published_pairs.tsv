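combined	single1	single2	reporter	published_category
hst3 hst4	hst3	hst4	CAN1	NA
hst3 hst4	hst3	hst4	his7-2	NA
hst3 hst4 rtt109	hst3 hst4	rtt109	CAN1	NA
hst3 hst4 rtt109	hst3 hst4	rtt109	his7-2	NA
hst3 hst4 H3K56R	hst3 hst4	H3K56R	CAN1	NA
hst3 hst4 H3K56R	hst3 hst4	H3K56R	his7-2	NA
rtt109 H3K56R	rtt109	H3K56R	CAN1	epistatic
rtt109 H3K56R	rtt109	H3K56R	his7-2	epistatic
msh2 rtt109	msh2	rtt109	CAN1	multiplicative
msh2 rtt109	msh2	rtt109	his7-2	synergistic
msh2 H3K56R	msh2	H3K56R	CAN1	multiplicative
msh2 H3K56R	msh2	H3K56R	his7-2	synergistic
msh2 asf1	msh2	asf1	CAN1	multiplicative
msh2 asf1	msh2	asf1	his7-2	synergistic
pol2-4 rtt109	pol2-4	rtt109	CAN1	multiplicative
pol2-4 rtt109	pol2-4	rtt109	his7-2	synergistic
pol2-4 H3K56R	pol2-4	H3K56R	CAN1	multiplicative
pol2-4 H3K56R	pol2-4	H3K56R	his7-2	synergistic
pol2-4 asf1	pol2-4	asf1	CAN1	multiplicative
pol2-4 asf1	pol2-4	asf1	his7-2	synergistic
pol3-5DV rtt109	pol3-5DV	rtt109	CAN1	multiplicative
pol3-5DV rtt109	pol3-5DV	rtt109	his7-2	synergistic
pol3-5DV H3K56R	pol3-5DV	H3K56R	CAN1	multiplicative
pol3-5DV H3K56R	pol3-5DV	H3K56R	his7-2	synergistic
pol3-5DV asf1	pol3-5DV	asf1	CAN1	multiplicative
pol3-5DV asf1	pol3-5DV	asf1	his7-2	synergistic
rev3 hst3 hst4	rev3	hst3 hst4	CAN1	epistatic
rev3 hst3 hst4	rev3	hst3 hst4	his7-2	epistatic
rev3 rtt109	rev3	rtt109	CAN1	NA
rev3 rtt109	rev3	rtt109	his7-2	NA
rtt101 hst3 hst4	rtt101	hst3 hst4	CAN1	NA
rtt101 hst3 hst4	rtt101	hst3 hst4	his7-2	NA
ctf18 hst3 hst4	ctf18	hst3 hst4	CAN1	NA
ctf18 hst3 hst4	ctf18	hst3 hst4	his7-2	NA
rad51 rtt109	rad51	rtt109	CAN1	NA
rad51 rtt109	rad51	rtt109	his7-2	epistatic
rad52 rtt109	rad52	rtt109	CAN1	NA
rad52 rtt109	rad52	rtt109	his7-2	epistatic
hst3 hst4 hst1	hst3 hst4	hst1	CAN1	NA
hst3 hst4 hst1	hst3 hst4	hst1	his7-2	NA
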