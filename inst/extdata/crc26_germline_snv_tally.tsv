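Samples	Exonic	synonymous_SNV	nonsynonymous_SNV	Intronic	Intergenic	Total
A2	21330	10965	10062	1236460	1995044	3571762
G2	20760	10795	9714	1204640	1954451	3489991
B2	21492	10999	10128	1279819	2092707	3724867
D2	21420	10962	10086	1270916	2102319	3733156
F2	21249	10972	9929	1268598	2092974	3712288
I2	21418	10998	10072	1264252	2091372	3706014
K2	21218	10928	9956	1270104	2102216	3724556
L2	21436	10991	10114	1247137	2084863	3712818
E2	21036	10875	9861	1268017	2080251	3696616
M2	21042	11073	10013	1270706	2116131	3736293
N2	21348	10944	10015	1277324	2113961	3744350
O2	21283	10961	10058	1269724	2111857	3734106
P2	21368	11002	9844	1265521	2087451	3703209
Q2	21185	10963	9986	1261794	2080751	3690318
R2	21289	11000	10062	1274074	2103933	3731153
S2	21380	11115	10129	1271932	2107524	3731078
V2	21578	10682	9703	1250046	1952921	3545933
X2	20709	11186	10118	1281237	2093248	3727021
Y2	21640	11047	9991	1276007	2089311	3715939
Z2	21372	11054	10066	1274270	2096588	3721788
AA2	21450	11164	10071	1268904	2094797	3714931
AB2	21608	10974	10054	1268904	2098742	3714117
AC2	21392	10989	10050	1267919	2092248	3707441
AD2	21357	11192	10274	1265748	2104546	3730655
AE2	21696	10960	10029	1274676	2104325	3716033
AF2	21280	10974	9948	1262132	2089116	3701519
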