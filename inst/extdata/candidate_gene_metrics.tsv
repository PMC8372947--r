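patient	rsnc	gene	mis_z	pli	del_single	cnv_score	chrom	start_1based	end_1based
P_000479	4.16	SLC8A1	2.23	1.00	-0.02	0.31	chr2	40624267	40646501
P_000512	8.31	TUBB	5.71	0.98	-2.85	-1.72	chr6	28005012	31683185
P_000512	8.31	GNL1	2.52	1.00	1.03	0.70	chr6	28005012	31683185
P_000512	8.31	GABBR1	4.98	1.00	1.36	1.23	chr6	28005012	31683185
P_000537	6.92	MAPK8	2.92	1.00	0.84	-2.25	chr10	49033586	52431193
P_000561	6.08	UFD1L	2.77	1.00	1.06	-2.53	chr22	18861209	21630630
P_000567	7.98	TBX2	1.75	0.99	-0.01	0.53	chr17	58076721	60362868
P_000567	7.98	USP32	3.55	1.00	-2.85	-0.93	chr17	58076721	60362868
P_002431	9.37	AKT3	4.03	1.00	-2.61	-1.20	chr1	243963527	244016804
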