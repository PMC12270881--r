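Samples	Exonic	frameshift_deletion	frameshift_insertion	Intronic	Intergenic	Total
A1	18	13	1	2772	3371	6783
G1	13	2	2	2117	2660	5260
B1	15	8	4	1892	2345	4692
D1	17	9	3	2374	3005	5916
F1	9	6	0	3048	3703	7453
I1	23	21	0	3213	4210	8183
K1	9	7	2	2350	3076	5972
L1	16	6	3	2676	3756	7048
E1	366	25	73	73444	80699	169616
M1	27	18	3	3089	4134	7962
N1	13	9	2	3054	3619	7315
O1	21	18	1	1540	1813	3775
P1	9	8	0	3274	3922	7875
Q1	15	8	3	2375	3055	5975
R1	184	44	21	45941	65547	123671
S1	19	11	4	4610	3710	12466
V1	14	11	0	2772	3102	6469
X1	5	2	0	2641	3179	6400
Y1	21	14	2	3515	4436	8771
Z1	15	7	4	4173	5993	11125
AA1	21	14	3	2827	3556	7033
AB1	21	15	3	3027	4112	7800
AC1	26	18	2	3692	4818	9361
AD1	20	16	2	2804	3375	6785
AE1	13	8	2	3167	3922	7768
AF1	41	22	2	2679	3637	6937
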