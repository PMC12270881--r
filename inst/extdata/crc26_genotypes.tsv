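Samples/genes	CPA6	ZNF888	SH3BP1	ANKRD16	ATN1	C4orf54
A2	het	het	hom_ref	hom_ref	het	hom_ref
G2	hom_ref	hom_ref	het	het	hom_ref	het
B2	hom_ref	het	het	hom_ref	hom_ref	het
D2	hom_ref	hom_ref	hom_ref	hom_ref	hom_ref	het
F2	hom_ref	hom_ref	het	hom_ref	hom_ref	het
I2	hom_ref	het	hom_ref	hom_ref	hom_ref	het
K2	hom_ref	het	hom_ref	het	hom_ref	het
L2	hom_ref	het	het	hom_ref	hom_ref	het
E2	hom_ref	hom_ref	hom_alt	hom_ref	hom_ref	hom_alt
M2	hom_ref	hom_ref	het	hom_ref	hom_ref	hom_alt
N2	hom_ref	het	het	het	hom_ref	hom_alt
O2	hom_ref	het	hom_alt	hom_alt	hom_ref	het
P2	hom_ref	hom_ref	het	hom_ref	hom_ref	hom_alt
Q2	hom_ref	hom_ref	het	hom_ref	hom_ref	hom_ref
R2	hom_ref	hom_ref	het	hom_ref	hom_ref	het
S2	hom_ref	hom_ref	hom_alt	hom_alt	hom_ref	het
V2	hom_ref	het	hom_ref	hom_ref	hom_ref	het
X2	hom_ref	het	het	hom_ref	het	het
Y2	hom_ref	hom_alt	het	hom_ref	hom_ref	hom_ref
Z2	hom_ref	hom_ref	het	het	hom_ref	hom_ref
AA2	hom_ref	het	het	het	hom_ref	het
AB2	hom_ref	hom_ref	hom_alt	hom_ref	hom_ref	het
AC2	hom_ref	hom_ref	hom_ref	hom_ref	hom_alt	hom_ref
AD2	hom_ref	hom_ref	hom_alt	hom_ref	hom_ref	het
AE2	hom_ref	hom_ref	hom_alt	hom_ref	hom_ref	hom_alt
AF2	hom_ref	hom_alt	hom_alt	het	hom_ref	het
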