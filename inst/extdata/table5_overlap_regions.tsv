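Chr	Peak (cM)	Interval lo	Interval hi	Left marker	Right marker
1B	47.6	47.1	48.1	IWA107	IWB65324
2A	49.55	46.6	52.5	IWB71456	IWA6478
2A	138.7	136.0	141.1	IWB72154	IWB64479
2B	50.85	45.3	56.4	wPt-4195	IWB72351
2B	64.3	58.2	70.4	IWB43195	IWA1664
3A	53.65	52.0	55.3	wmc505	IWB71974
3B	55.95	48.6	63.3	IWA6192	IWB64601
4B	24.2	17.6	30.8	IWB64823	IWB58052
5B	100.55	94.5	106.6	IWA1408	IWB35880
6A	57.95	56.8	59.1	IWB73438	IWB51739
7A	163.65	155.9	171.4	IWB7649	IWB27947
7B	7.55	4.9	10.2	IWB72000	IWB6355
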