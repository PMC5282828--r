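gene	mode	chrom	pos	ref	alt	rsid	effect_class	transcript_id	aa_change	aa_length	cadd	maf_esp6500_ea	maf_kg_eur	maf_exac_nfe	hom_ref_count	hom_ref_n	immediate_stop	splice_coding_2bp	functional	genetic
ANKRD30A	CH	10	37438759	G	T	.	stopgain	NM_052997	p.E487X	1341	35.0	.	.	.	.	.	.	.	.	.
ANKRD30A	CH	10	37508648	A	AT	.	frameshift	NM_052997	p.Q1280fs	1341	24.2	.	.	0.000031	0	32647	TRUE	.	.	.
ARSB	HZ	5	78281383	T	TA	rs138279020	splice	NM_198709	c.190-2insT	533	2.2	.	.	.	.	.	.	TRUE	S	neuroX
c11orf21	HZ	11	2321829	C	T	rs74048215	stopgain	NM_001142946	p.W69X	178	35.0	.	.	0.00037	0	32647	.	.	.	.
CALML4	HZ	15	68497597	G	A	rs11071990	stopgain	NM_001031733	p.R40X	120	25.9	.	.	0.0075	1	32647	.	.	.	.
CAPS2	HZ	12	75687045	C	CTATTTGAT	.	stopgain	NM_001286547	p.L321X	382	33.0	.	.	0.0068	4	32647	.	.	.	.
CD36	CH	7	80285955	C	T	.	stopgain	NM_001127444	p.Q74X	472	26.5	.	.	0.000075	0	32647	.	.	.	GRIP
CD36	CH	7	80302705	C	T	.	missense	NM_001127444	p.P412S	472	25.9	.	.	0.00011	0	32647	.	.	.	.
COL6A5	CH	3	130132401	C	T	rs190283135	stopgain	NM_001278298	p.Q1559X	2611	38.0	.	.	0.0012	0	32647	.	.	.	.
COL6A5	CH	3	130107827	G	A	.	missense	NM_001278298	p.V756M	2611	23.0	.	.	0.0032	0	32647	.	.	.	.
DIS3	CH	13	73355096	G	A	rs201493043	stopgain	NM_014953	p.Q92X	958	37.0	.	.	0.000045	0	32647	.	.	Mm	.
DIS3	CH	13	73333935	A	G	rs141067458	stoploss	NM_014953	p.X959Q	958	14.1	.	.	0.0022	0	32647	.	.	.	.
FAM71A	HZ	1	212799882	A	T	rs143861665	stopgain	NM_153606	p.K555X	594	36.0	.	.	0.0080	2	32647	.	.	Mm	.
FAM83A	CH	8	124195352	G	T	rs148011353	stopgain	NM_032899	p.G86X	434	26.2	.	.	0.0023	2	32647	.	.	.	PPMI
FAM83A	CH	8	124195506	T	G	.	missense	NM_032899	p.V137G	434	25.6	.	.	.	.	.	.	.	.	.
GH2	HZ	17	61957946	C	T	rs150668018	stopgain	NM_022557	p.W214X	256	26.8	.	.	0.0033	1	32647	.	.	.	.
GPATCH2L	HZ	14	76644266	C	T	rs117516637	stopgain	NM_017972	p.R362X	482	18.8	.	.	0.0053	1	32647	.	.	Mp,Mm	PPMI
KALRN	HZ	3	124303696	C	T	rs56407180	stopgain	NM_007064	p.R10X	1289	37.0	.	.	0.0039	0	32647	.	.	Mp	.
KCNK16	HZ	6	39282816	G	A	rs138573996	stopgain	NM_001135107	p.Q251X	322	9.5	.	.	0.0044	2	32647	.	.	Mm	.
MNS1	CH	15	56736045	G	A	.	stopgain	NM_018365	p.Q232X	495	38.0	.	.	.	.	.	.	.	Mm	.
MNS1	CH	15	56748680	G	A	.	stopgain	NM_018365	p.Q89X	495	37.0	.	.	0.00003	0	32647	.	.	.	.
OR7G3	HZ	19	9236969	G	A	rs61751875	stopgain	NM_001001958	p.R220X	312	35.0	.	.	0.0015	1	32647	.	.	Mm	.
PCDHA9	HZ	5	140229907	C	G	.	stopgain	NM_014005	p.Y609X	950	34.0	.	.	0.000046	0	32647	.	.	Mm	.
PTCHD3	HZ	10	27688101	G	A	rs142646098	stopgain	NM_001034842	p.R476X	767	34.0	.	.	0.0097	6	32647	.	.	Mp,Mm	.
PTPRH	CH	19	55697712	G	A	rs147881000	stopgain	NM_002842	p.Q887X	1115	36.0	.	.	0.0039	1	32647	.	.	S,Mm	neuroX
PTPRH	CH	19	55716715	C	A	rs201517965	stopgain	NM_002842	p.E200X	1115	26.0	.	.	0.00003	0	32647	.	.	.	.
PZP	CH	12	9321534	G	A	rs145240281	stopgain	NM_002864	p.R680X	1482	32.0	.	.	0.0085	4	32647	.	.	.	.
PZP	CH	12	9333626	G	A	rs117889746	stopgain	NM_002864	p.Q598X	1482	36.0	.	.	0.00021	0	32647	.	.	.	.
SSPO	HZ	7	149493519	C	T	rs57595625	stopgain	NM_198455	p.Q2199X	5150	10.4	.	.	0.00011	0	32647	.	.	.	.
SVOPL	HZ	7	138341219	G	A	rs117871806	stopgain	NM_174959	p.R18X	492	38.0	.	.	0.0035	0	32647	.	.	Mp,Mm	.
TCHHL1	HZ	1	152058192	G	A	rs150014958	stopgain	NM_001008536	p.Q656X	904	35.0	.	.	0.00037	0	32647	.	.	Mp	.
TMEM134	HZ	11	67235051	G	A	rs143199541	stopgain	NM_001078650	p.R84X	195	34.0	.	.	0.0070	3	32647	.	.	S	.
UHRF1BP1L	HZ	12	100433523	T	A	.	stopgain	NM_015054	p.K1376X	1464	35.0	.	.	.	.	.	.	.	Mm	neuroX
VPS13C	CH	15	62174851	C	A	.	stopgain	NM_017684	p.E3147X	3628	55.0	.	.	.	.	.	.	.	S,Mm	neuroX,GWAS
VPS13C	CH	15	62305257	C	CTCTG	.	frameshift	NM_017684	p.R226fs	3628	27.4	.	.	.	.	.	TRUE	.	.	.
ZNF543	HZ	19	57838058	G	A	rs150392165	stopgain	NM_213598	p.W68X	600	25.0	.	.	0.0060	1	32647	.	.	Mp,Mm	.
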