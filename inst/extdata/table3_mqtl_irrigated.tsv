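Chr	MQTL	Peak (cM)	CI (95%)	N QTL	N studies	Traits	Left marker	Right marker
1B	YIELD_MQTL1B.1_I	42.27	8.43	4	4	HI, SLNS, TGW	IWB31228	IWB57547
2A	YIELD_MQTL2A.1_I	49.12	3.65	3	2	TGW, GNM	IWB54033	IWB73216
2A	YIELD_MQTL2A.2_I	105.91	5.5	2	2	HI, GW	IWB73852	IWB40575
2A	YIELD_MQTL2A.3_I	139.11	3.74	2	2	TGW, GY	IWB72154	IWB7051
2B	YIELD_MQTL2B.1_I	56.12	15.49	3	2	TGW, HI	IWB69396	IWB25893
2B	YIELD_MQTL2B.2_I	102.87	6.33	4	2	GNPS, GWPS, TGW	IWA772	IWB15509
2B	YIELD_MQTL2B.3_I	140.5	10.56	3	2	HI, GY	wPt-11586	IWB22762
3A	YIELD_MQTL3A.1_I	53.85	2.58	7	2	GNPS, TGW, SW, SL, GY	IWB68183	IWB71974
3A	YIELD_MQTL3A.2_I	75.82	6.09	2	2	GY, TGW	IWB6187	IWA234
3B	YIELD_MQTL3B.1_I	67.78	19.82	3	3	HI, GNPS, SLNS	wPt-10530	IWB1111
3B	YIELD_MQTL3B.2_I	160.29	11.99	3	3	HI, TGW, SNM	IWB50437	IWB10030
3B	YIELD_MQTL3B.3_I	206.94	3.9	8	3	TGW, GNPS, SW, GY, HI	IWB152	IWB8780
4A	YIELD_MQTL4A.1_I	118.62	7.17	3	2	GY, SL, HI	wmc283	IWB1566
4B	YIELD_MQTL4B.1_I	26.92	11.02	4	2	TGW, TW, SNP	wmc710	IWB58189
4B	YIELD_MQTL4B.2_I	48.41	12.2	2	2	TGW, SL	IWB68116	IWB74693
4B	YIELD_MQTL4B.3_I	80.85	4.86	3	2	TGW, GY	IWB52747	IWB47175
5A	YIELD_MQTL5A.1_I	102.83	11.68	3	2	TGW, GY	IWB33346	IWB47051
5A	YIELD_MQTL5A.2_I	173.27	2.11	3	2	TGW, SL	fcp650	IWB68028
5B	YIELD_MQTL5B.1_I	44.52	18.42	4	2	GNPS, SL, TGW	IWB64981	IWB56439
5B	YIELD_MQTL5B.2_I	100.76	7.57	5	3	GNPS, GWPS, HI	IWB12094	IWB21820
6A	YIELD_MQTL6A.1_I	56.81	6.63	5	3	GNPS, TGW	IWB60744	IWB39171
6B	YIELD_MQTL6B.1_I	53.39	4.71	7	3	SLNS, SNP, HI, TGW	barc14	IWB56048
6B	YIELD_MQTL6B.2_I	130.89	5.73	3	3	GY, SNP, TGW	IWB7417	IWB19986
7A	YIELD_MQTL7A.1_I	81.89	10.29	4	2	TW, GWPS, GNPS, TGW	IWB27983	IWA4180
7A	YIELD_MQTL7A.2_I	119.88	14.89	2	2	TGW, GY	IWB1318	IWB29333
7A	YIELD_MQTL7A.3_I	164.14	9.43	3	3	TGW, SLNS	IWB7435	IWB52522
7B	YIELD_MQTL7B.1_I	9.05	4.46	7	4	HI, GNM, SLNS, GY	IWB30314	IWB6455
7B	YIELD_MQTL7B.2_I	50.13	9.01	3	2	SLNS, SL, SNP	IWB34143	IWA7589
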