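Samples	Exonic	Frameshiftdeletion	Frameshiftinsertion	Intronic	Intergenic	Total
A2	565	99	59	355446	460273	898904
G2	523	106	57	356572	458147	896558
B2	572	89	65	399575	528756	1021744
D2	561	94	60	400081	532223	1026546
F2	577	96	66	394956	525037	1012445
I2	527	92	68	384517	511058	985970
K2	535	91	56	386048	515689	992875
L2	544	93	64	388004	513220	992320
E2	571	98	60	371785	493067	952055
M2	587	100	74	385958	510992	987349
N2	581	106	61	378004	504409	971206
O2	572	100	64	392786	521801	1006409
P2	523	78	50	368616	492902	948192
Q2	563	101	60	375047	496754	959325
R2	561	86	63	383477	507169	980824
S2	582	97	71	379755	506167	975154
V2	512	82	56	373290	480130	941224
X2	541	78	64	383130	504031	976614
Y2	561	86	61	398658	524861	1016640
Z2	564	93	59	385988	511170	987518
AA2	578	92	67	381971	504687	976361
AB2	563	102	65	373469	497559	958528
AC2	566	103	65	380856	505078	975331
AD2	591	105	65	380984	505687	975705
AE2	580	103	63	381219	509810	980485
AF2	588	98	66	382133	504721	976807
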