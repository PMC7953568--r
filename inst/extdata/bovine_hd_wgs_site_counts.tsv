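chrom	length_mb	n_reference	n_target	pct_to_impute
1	158.44	1965500	36424	98.15
2	136.15	1594559	30832	98.07
3	121.00	1396284	28583	97.95
4	119.86	1514666	26434	98.25
5	120.05	1350367	25150	98.14
6	117.80	1461356	28480	98.05
7	110.64	1297470	25926	98.00
8	113.24	1309174	26848	97.95
9	104.64	1281310	25088	98.04
10	103.26	1219761	22454	98.16
11	106.98	1246742	24204	98.06
12	87.20	1121539	19004	98.31
13	83.45	947897	17794	98.12
14	82.37	991359	20322	97.95
15	84.96	1120179	18849	98.32
16	80.98	974221	18626	98.09
17	73.15	928571	17803	98.08
18	65.81	753566	14541	98.07
19	63.42	713820	13370	98.13
20	71.96	910476	16074	98.23
21	69.84	857266	16234	98.11
22	60.76	729871	13479	98.15
23	52.50	774175	12292	98.41
24	62.30	790397	14192	98.20
25	42.34	521876	9425	98.19
26	51.98	655622	11869	98.19
27	45.61	642015	10030	98.44
28	45.91	636577	9991	98.43
29	51.09	687868	10717	98.44
Overall	2487.69	30394484	565035	98.14
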