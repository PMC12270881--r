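Samples	Exonic	synonymous_SNV	nonsynonymous_SNV	Stopgain	Intronic	Total	Intergenic
A1	227	68	152	7	6252	21306	12920
G1	249	72	158	15	6019	20090	11927
B1	414	132	258	22	7832	24640	14052
D1	533	247	262	23	8719	27061	15300
F1	619	179	409	25	12160	35752	19487
I1	545	173	336	31	11315	36516	21284
K1	386	106	261	14	9870	33730	20316
L1	433	120	288	23	9793	37074	18094
E1	1947	558	1318	61	41822	113951	59500
M1	376	105	255	12	8755	29232	17438
N1	228	72	139	14	5785	19622	11757
O1	535	137	382	12	5162	16082	8691
P1	279	80	186	10	6911	22208	12907
Q1	248	69	159	18	6352	22205	13498
R1	7144	3507	3521	54	376249	1072787	591740
S1	406	133	270	20	10539	35962	21713
V1	290	76	197	15	6581	20391	11633
X1	264	98	160	3	6760	21771	12673
Y1	380	114	248	17	10885	33840	19551
Z1	452	119	300	13	12378	39770	23283
AA1	438	109	298	19	9534	31315	18500
AB1	309	139	187	7	8615	30038	18289
AC1	473	111	318	13	12009	38136	22047
AD1	325	104	196	14	7742	25855	15368
AE1	347	142	219	20	9293	30350	17967
AF1	1467	362	1060	27	16982	53818	30044
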