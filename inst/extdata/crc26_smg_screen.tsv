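Gene	Muts	Total_Muts	Sample_affected	Sample_percent (%)	Pvalue
ATAD3B	2	4038	2	7.69%	0.02098
CCDC27	1	4038	1	3.85%	0.19955
AJAP1	1	4038	1	3.85%	0.13003
STPG1	1	4038	1	3.85%	0.13626
INPP5B	1	4038	1	3.85%	0.30121
CYP4X1	1	4038	1	3.85%	0.15893
LRRC8C	1	4038	1	3.85%	0.24077
EXTL2	1	4038	1	3.85%	0.10838
NBPF20	2	4038	2	7.69%	0.57100
PPIAL4H	1	4038	1	3.85%	0.05415
NUDT4B	5	4038	5	19.23%	0.32450
HRNR	3	4038	3	11.54%	0.07315
THBS3	2	4038	1	3.85%	0.04261
FCRL5	1	4038	1	3.85%	0.29308
ASTN1	1	4038	1	3.85%	0.35835
KIF21B	1	4038	1	3.85%	0.43000
ADIPOR1	1	4038	1	3.85%	0.11962
PIK3C2B	1	4038	1	3.85%	0.45588
OBSCN	4	4038	4	15.38%	0.40588
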