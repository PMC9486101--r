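Chr	MQTL	Peak (cM)	CI (95%)	N QTL	N studies	Traits	Left marker	Right marker
1A	YIELD_MQTL1A.1_D	28.78	5.94	5	2	HI, SLNS, GYPS	IWB14137	IWB68107
1A	YIELD_MQTL1A.2_D	119.16	8.12	8	2	TGW, SNM, GNM	dupw38	barc213
1A	YIELD_MQTL1A.3_D	141.65	2.48	4	2	TGW	tPt-7724	IWB64946
1B	YIELD_MQTL1B.1_D	47.7	0.53	24	7	GL, TGW, GNPS, GW, GY, GNP, SLNS, GNM, GYPS	IWB8804	IWB12485
1B	YIELD_MQTL1B.2_D	71.45	5.31	5	3	GNP, GY, GNM, TGW, SNP	IWB51605	IWB6504
1B	YIELD_MQTL1B.3_D	124.34	2.07	12	4	GY, GNP, TGW, GNSL, GNS, SNP, SLNS	wPt-5034	IWB9116
2A	YIELD_MQTL2A.1_D	35.9	0.38	7	3	GL, TGW, GP, GY, GW	IWB1365	SBG_1442
2A	YIELD_MQTL2A.2_D	51.89	5.38	4	2	TGW, HI	IWB146	IWB8363
2A	YIELD_MQTL2A.3_D	88.61	0.84	10	2	SNP, TGW, GW, GL	gwm275	IWA3194
2A	YIELD_MQTL2A.4_D	139.29	7.4	2	2	TGW, SNP	IWB72154	IWB71648
2A	YIELD_MQTL2A.5_D	203.93	3.38	8	4	SNP, SLNS, GNP, GA, GNPS, GY	IWB12337	IWB29474
2B	YIELD_MQTL2B.1_D	28.89	7.1	5	3	SNM, GYPS, HI, GNPS	IWB43306	IWB12400
2B	YIELD_MQTL2B.2_D	51.04	6.27	7	2	GNSL, SLNS, HI, GY	IWB55936	IWB13631
2B	YIELD_MQTL2B.3_D	69.59	11.86	2	2	SL, GY	IWB46777	IWB53866
2B	YIELD_MQTL2B.4_D	89.08	3.55	4	2	GP, GNPS, GA, TGW	IWB58691	IWB59170
2B	YIELD_MQTL2B.5_D	182.93	0.68	5	2	GP, TGW	IWB166	wPt-3755
3A	YIELD_MQTL3A.1_D	21.21	0.8	3	3	TGW, GP, GL	IWB26667	IWB73310
3A	YIELD_MQTL3A.2_D	55.55	4.2	8	4	TGW, GW, SNM, SW, GNPS, HI	IWB74013	IWB71974
3A	YIELD_MQTL3A.3_D	91.82	3.84	2	2	GY, TGW	IWB67254	IWB72074
3A	YIELD_MQTL3A.4_D	130.68	2.52	2	2	TGW, SNP	IWB22148	IWA799
3B	YIELD_MQTL3B.1_D	9.8	3.07	22	5	TGW, GYPS, GNPS, GY, GNSL, GNP, GNM	cfb6045	cfb6021
3B	YIELD_MQTL3B.2_D	25.42	6.34	4	3	GNP, GY, GYPS	IWB64404	SBG_116252
3B	YIELD_MQTL3B.3_D	55.17	9.24	6	2	GY, GNPS, TGW, SNM, SW	IWB21831	IWB41640
3B	YIELD_MQTL3B.4_D	194.66	2.75	3	2	TGW, GNSL	SBG_109559	IWB73613
4A	YIELD_MQTL4A.1_D	66.98	9.9	2	2	GNPS, TGW	IWB2382	IWB18669
4A	YIELD_MQTL4A.2_D	129.69	9.54	4	3	GY, GL	IWB44140	wPt-1091
4B	YIELD_MQTL4B.1_D	24.39	8.37	4	3	GNPS, GNM, TGW, GW	IWB72973	IWB73302
4B	YIELD_MQTL4B.2_D	62.12	2.09	12	6	TGW, GNPS, SNM, GY, HI, SLNS, GNSL, GNP	IWB34975	gwm495
4B	YIELD_MQTL4B.3_D	68.83	4.06	2	2	TGW, GW	IWB17754	IWB62565
4B	YIELD_MQTL4B.4_D	94.45	6.7	7	3	HI, GNM, GY, TGW	IWB71653	IWB7100
5A	YIELD_MQTL5A.1_D	36.63	7.14	4	3	GNPS, GL, GNM, SW	IWB22285	SBG_117464
5A	YIELD_MQTL5A.2_D	65.46	9.32	2	2	GY, SLNS	IWB28350	barc40
5A	YIELD_MQTL5A.3_D	82.78	9.2	2	2	TGW, GNPS	wPt-4248	IWB6959
5A	YIELD_MQTL5A.4_D	146.45	2.43	5	3	GNP, GW, TGW	IWB55921	IWA4276
5B	YIELD_MQTL5B.1_D	104.63	11.79	6	4	HI, TGW, GY	IWB64691	IWA4094
5B	YIELD_MQTL5B.2_D	161.97	8.18	3	2	GA, GNPS, GL	IWB162	wPt-3213
6A	YIELD_MQTL6A.1_D	3.1	2.52	2	2	TGW	IWB63240	IWA7288
6A	YIELD_MQTL6A.2_D	58.04	2	2	2	TGW	IWB73438	IWB66638
6A	YIELD_MQTL6A.3_D	87.6	2.37	4	3	GY, GW, TW, TGW	IWA8431	barc204
6B	YIELD_MQTL6B.1_D	33.73	17.9	2	2	TGW	IWA5507	gwm508
6B	YIELD_MQTL6B.2_D	74.09	5.15	5	3	TGW, GA, TW	IWB63659	IWB571
6B	YIELD_MQTL6B.3_D	101.13	0.12	18	6	SLNS, GA, GNPS, GL, GP, TGW	IWB70152	wPt-3581
7A	YIELD_MQTL7A.1_D	60.93	9.94	3	3	GYPS, TW, SLNS	IWB59818	IWB64911
7A	YIELD_MQTL7A.2_D	94.92	9.35	7	5	GNPS, GL, SNP, HI, SNM, GY	IWB47576	IWB7751
7A	YIELD_MQTL7A.3_D	157.17	25.96	3	3	TGW, GY, SL	IWB3767	IWA4620
7B	YIELD_MQTL7B.1_D	9.02	4.55	8	5	TGW, GY, HI	IWB27108	IWB6455
7B	YIELD_MQTL7B.2_D	89.61	3.87	10	5	GNPS, GYPS, TGW, GY	IWB73443	IWB63652
7B	YIELD_MQTL7B.3_D	142.8	1.35	4	2	SLNS, TGW, GL	IWB68926	IWB17987
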