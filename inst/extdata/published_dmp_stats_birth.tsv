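probe_id	gene	chr	genomic_location	position	std_beta	p	q
cg04941418	PACSIN1	6	5′UTR	34493129	-0.34	1.10E-08	0.005
cg11074746	MEMO1	2	TSS1500	32236343	0.31	1.77E-07	0.02
cg00335219	NA	16	NA	86012305	0.27	1.79E-07	0.02
cg07395930	CLSTN1	1	Body	9791419	-0.31	3.84E-07	0.02
cg01589998	FOXN4	12	Body	109729478	0.31	3.92E-07	0.02
cg13978601	PPP2R4	9	Body	131905041	-0.31	4.10E-07	0.02
cg23361356	SLC9A3	5	Body	508834	-0.31	4.17E-07	0.02
cg27020216	SGEF	3	Body	153840347	0.29	8.35E-07	0.03
cg14632140	LMO3	12	5′UTR	16758112	0.29	9.82E-07	0.03
cg08080985	C9orf95	9	Body	77703079	0.30	1.07E-06	0.03
cg20685020	ATP6V0B	1	5′UTR	44440676	0.30	1.34E-06	0.03
cg25229198	ADAMTS6	5	Body	64660684	-0.30	1.38E-06	0.03
cg05968179	USP6NL	10	Body	11505706	-0.29	1.42E-06	0.03
cg01009697	NTRK2	9	TSS1500	87283470	0.29	1.56E-06	0.03
cg19026817	NA	20	NA	56782259	-0.29	1.64E-06	0.03
cg05116255	ANKRD30A	10	TSS1500	37413782	-0.29	1.85E-06	0.03
cg04799664	NLRC5	16	5′UTR	57053850	-0.29	1.85E-06	0.03
cg07746699	IFT140	16	TSS200	1662305	0.30	1.87E-06	0.03
cg02290110	SHC2	19	TSS1500	461808	0.29	1.91E-06	0.03
cg06951646	TRRAP	7	Body	98586548	-0.29	1.92E-06	0.03
cg02052845	HGS	17	Body	79658835	-0.29	2.00E-06	0.03
cg05033322	ATM	11	TSS1500	108093245	0.29	2.08E-06	0.03
cg02404636	SFI1	22	TSS1500	31891804	0.29	2.10E-06	0.03
cg05620865	AP3B1	5	Body	77588408	-0.29	2.22E-06	0.03
cg14291256	MMP21	10	Body	127461065	-0.29	2.25E-06	0.03
cg12593849	STX12	1	3′UTR	28150710	-0.29	2.31E-06	0.03
cg10844884	ZNF22	10	Body	45498904	-0.29	2.32E-06	0.03
cg27242945	CAV1	7	1st exon	116165134	0.28	2.35E-06	0.03
cg13562386	TAGLN2	1	TSS1500	159895724	0.29	2.36E-06	0.03
cg25767859	PKD1L1	7	Body	47859324	-0.29	2.37E-06	0.03
cg12202228	FNDC3B	3	Body	171871829	-0.29	2.52E-06	0.03
cg20056324	NEUROD4	12	TSS200	55413610	0.29	2.60E-06	0.03
cg27122536	FOXF1	16	1st exon	86544658	0.29	2.67E-06	0.03
cg14661886	PRRT3	3	TSS200	9994197	0.29	2.75E-06	0.03
cg27596068	SERPINH1	11	TSS1500	75272301	-0.28	2.77E-06	0.03
cg23088142	NA	3	NA	137531265	0.29	2.99E-06	0.03
cg08625693	DLG3	X	Body	69674126	-0.26	3.09E-06	0.03
cg05463325	RAB4A	1	TSS1500	229406534	0.29	3.23E-06	0.04
cg01894322	PPP1R1B	17	Body	37789575	-0.28	3.38E-06	0.04
cg13138952	RPH3AL	17	Body	236013	-0.29	3.39E-06	0.04
cg01338630	RASD2	22	3′UTR	35948166	-0.27	3.77E-06	0.04
cg22409100	SLC8A1	2	TSS1500	40658918	0.14	4.01E-06	0.04
cg24954684	CLIP1	12	TSS1500	122907641	0.27	4.08E-06	0.04
cg22467567	IGFBP5	2	5′UTR	217559885	0.28	4.39E-06	0.04
cg25179876	NRP1	10	Body	33483109	-0.19	4.47E-06	0.04
cg04388666	CCDC85C	14	TSS1500	100072073	0.28	4.61E-06	0.04
cg13244417	TMTC4	13	TSS200	101327186	0.28	4.75E-06	0.04
cg16661000	HAPLN3	15	5′UTR	89437710	0.27	4.81E-06	0.04
cg00276455	NA	6	NA	54904638	-0.28	4.82E-06	0.04
cg08261702	LOC728743	7	Body	150103112	0.25	5.02E-06	0.04
cg05168344	LZTR1	22	Body	21340160	-0.28	5.07E-06	0.04
cg02725795	FAM175A	4	Body	84405871	0.27	5.18E-06	0.04
cg20336014	MGEA5	10	TSS200	103578255	0.27	5.49E-06	0.04
cg26047334	TNS1	2	5′UTR	218785909	0.25	5.56E-06	0.04
cg18769584	LZTFL1	3	3′UTR	45866619	-0.27	5.64E-06	0.04
cg13083436	LUZP2	11	TSS200	24518414	0.28	5.74E-06	0.04
cg23530543	HEPN1	11	TSS1500	124788414	-0.28	5.98E-06	0.04
cg02957771	FBXO31	16	Body	87380349	-0.27	6.13E-06	0.04
cg17396676	EPS15L1	19	TSS1500	16583990	-0.28	6.56E-06	0.04
cg09278687	TBX6	16	Body	30100430	-0.28	6.91E-06	0.04
cg20643362	C19orf12	19	1st exon	30206369	0.27	7.37E-06	0.04
cg10395806	CTTN	11	Body	70280601	-0.28	7.43E-06	0.04
cg00877150	BCOR	X	5′UTR	39972039	-0.27	7.52E-06	0.04
cg20319698	LRRFIP1	2	Body	238644099	-0.27	7.73E-06	0.04
cg14712611	ANK2	4	5′UTR	113739379	0.27	7.74E-06	0.04
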