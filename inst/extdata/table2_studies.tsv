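study_id	cross	pop_type	pop_size	traits	n_qtl	irrigated_and_rainfed	n_env
S01	Zavitan x Svevo	RIL	137	TGW	16	yes	4
S02	Svevo x Ciccio	RIL	120	TGW, GYPS, GNPS	30	no	5
S03	Iran_249 x Zardak	RIL	118	TGW, GL, GW, GP, GA	51	no	3
S04	Omrabi 5 x PI600545	RIL	114	TGW, TW	3	no	4
S05	Ben x PI 41025	RIL	200	GWPS, TGW, SLNS, GNPS, SL	17	no	2
S06	Svevo x Y12-3	RIL	208	TGW	39	yes	5
S07	Saragolla x 02-5B-318	RIL	135	GYPS	29	no	3
S08	Ofanto x Senatore Cappelli	RIL	98	GNSL, SNP, GNPS, SLNS	52	no	2
S09	Oste-Gata x Massara-1	F2:3	151	TGW, GWPS, GNPS, SNM, HI	17	yes	2
S10	Kofa x Svevo	RIL	249	TGW, GNM, GNPS	64	yes	16
S11	Colosseo x Lloyd; Meridiano x Claudio	RIL	176	TGW	5	no	2
S12	Kofa x Svevo	RIL	249	GY	10	yes	16
S13	Liberdur x Anco Marzio	RIL	133	GL, GW, GA, TGW	31	no	3
S14	Duilio x Avonlea	RIL	134	GYPS	7	no	2
S15	Neodur, Claudio, Colosseo, Rascon/Tarro	MAGIC	338	GY	2	no	8
S16	Omrabi5 x Belikh2	RIL	114	TGW, GA, GL, GW	8	no	2
S17	PDW 233 x Bhalegaon 4	RIL	140	TW, TGW, GY, SL, SLNS, GNPS, GWPS	44	no	4
S18	Langdon x G18-16	RIL	152	GY, HI	34	yes	2
S19	H52 x Langdon	F2	150	GNP, GNSL, GY, SNP, SLNS, GNPS	44	no	1
S20	Omrabi5 x Belikh2	RIL	114	SW, SL, GNPS, TGW, GY, HI	89	yes	4
S21	UC1113 x Kofa	RIL	93	HI, GNPS, SLNS, GY, GNP, GNSL, SNM, SNP, TGW	93	no	6
S22	Simeto x Molise Colli	RIL	136	GL, TGW, GW	8	no	2
S23	KU7309 x KU8736A	F2	144	SLNS, SNP, TGW	5	no	1
S24	Langdon x G18-16	RIL	150	TGW	4	no	2
S25	Four RIL populations	RIL	576	SNM, TGW, GY	23	yes	4
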