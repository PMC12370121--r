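rsid	chromosome	gene	odds_ratio	pmids
rs2476601	1	PTPN22	1.81	15208781, 20453842
rs9557321	13	CLYBL	1.73	24532677
rs113066392	7	GTF2IRD1-NCF1	1.43	33310728, 28135245, 27272985
rs138193887	11	CUL5	1.21	33310728, 35088123, 22446963
rs3753389	1	CD244	1.30	18794858
rs909685	22	SYNGR1	1.14	23143596, 33310728
rs11933540	4	RBPJ	1.15	24390342, 23143596, 20453842
rs16903108	8	PVT1	1.15	35088123, 23143596
rs911760	9	PLGRKT	1.15	35088123
rs940825	7	AGR3-AHR	1.13	35088123
rs2867461	4	ANXA3	1.13	22446963
rs11574914	9	CCL21	1.12	35088123, 23143596, 22446963, 20453842
rs13031237	2	REL	1.12	19503088
rs6681482	1	TNFSF4	1.12	24532676, 35088123, 24390342
rs705700	12	CDK2	1.09	24390342, 33310728
rs34480360	16	ZNF689	1.09	33310728, 35088123
rs2300373	21	IFNGR2	1.09	35088123, 33310728, 23143596
rs5754104	22	UBE2L3-YDJC	1.09	23143596, 35088123, 33310728
rs1427749	12	SCAF11	1.08	35088123
rs9979383	21	RUNX1	1.08	23143596, 35088123, 33310728, 23143596
rs866205108	18	TNFRSF1A	1.10	35088123
rs1885013	14	RAD51B	1.11	24390342, 33310728
rs11375064	17	KSR1	0.93	23143596, 35088123, 24390342
rs11777380	8	CCN4	0.92	35088123
rs2671692	10	WDFY4	0.92	23143596, 22446963, 35088123
rs660442	11	BAD	0.90	33310728, 35088123
rs6032662	20	CD40	0.90	19898481, 35088123, 22446963, 23143596
rs6495979	15	RasGRP1	0.88	23143596, 35088123, 24390342, 33310728
rs10790268	11	CXCR5	0.87	24390342
rs1571878	6	CCR6	0.86	23143596, 22446963, 20453842
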