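# name	P
# hit_threshold	30
# consensus	VTYNTLIDGLCKAGKLDEAIELFEEMKEKGVKPNV
residue	1	2	3	4	5	6	7	8	9	10	11	12	13	14	15	16	17	18	19	20	21	22	23	24	25	26	27	28	29	30	31	32	33	34	35
A	-2.321928	-2.321928	-2.321928	-2.321928	-2.321928	-2.321928	-2.321928	-2.321928	2.378512	-2.321928	-2.321928	-2.321928	3.485427	2.378512	-2.321928	-2.321928	-2.321928	-2.321928	3.485427	-2.321928	-2.321928	-2.321928	-2.321928	-2.321928	-2.321928	-2.321928	-2.321928	-2.321928	-2.321928	2.378512	-2.321928	-2.321928	-2.321928	-2.321928	-2.321928
C	-2.321928	-2.321928	-2.321928	-2.321928	-2.321928	-2.321928	-2.321928	-2.321928	-2.321928	-2.321928	4.017922	-2.321928	-2.321928	-2.321928	-2.321928	-2.321928	-2.321928	-2.321928	-2.321928	-2.321928	-2.321928	-2.321928	-2.321928	-2.321928	-2.321928	-2.321928	-2.321928	-2.321928	-2.321928	-2.321928	-2.321928	-2.321928	-2.321928	-2.321928	-2.321928
D	-2.321928	-2.321928	-2.321928	-2.321928	-2.321928	-2.321928	-2.321928	3.485427	-2.321928	-2.321928	-2.321928	-2.321928	-2.321928	-2.321928	-2.321928	-2.321928	3.485427	2.378512	-2.321928	-2.321928	2.378512	-2.321928	-2.321928	2.378512	2.378512	-2.321928	-2.321928	2.378512	-2.321928	-2.321928	-2.321928	-2.321928	-2.321928	-2.321928	-2.321928
E	-2.321928	-2.321928	-2.321928	-2.321928	-2.321928	-2.321928	-2.321928	2.378512	-2.321928	-2.321928	-2.321928	-2.321928	-2.321928	-2.321928	-2.321928	-2.321928	2.378512	3.485427	-2.321928	-2.321928	3.485427	-2.321928	-2.321928	3.485427	3.485427	-2.321928	-2.321928	3.485427	-2.321928	-2.321928	-2.321928	-2.321928	-2.321928	-2.321928	-2.321928
F	-2.321928	-2.321928	1.432959	-2.321928	-2.321928	-2.321928	-2.321928	-2.321928	-2.321928	-2.321928	-2.321928	-2.321928	-2.321928	-2.321928	-2.321928	-2.321928	-2.321928	-2.321928	-2.321928	-2.321928	-2.321928	-2.321928	3.485427	-2.321928	-2.321928	-2.321928	-2.321928	-2.321928	-2.321928	-2.321928	-2.321928	-2.321928	-2.321928	-2.321928	-2.321928
G	-2.321928	-2.321928	-2.321928	-2.321928	-2.321928	-2.321928	-2.321928	-2.321928	3.485427	-2.321928	-2.321928	-2.321928	2.378512	3.485427	-2.321928	-2.321928	-2.321928	-2.321928	2.378512	-2.321928	-2.321928	-2.321928	-2.321928	-2.321928	-2.321928	-2.321928	-2.321928	-2.321928	-2.321928	3.485427	-2.321928	-2.321928	-2.321928	-2.321928	-2.321928
H	-2.321928	-2.321928	-2.321928	-2.321928	-2.321928	-2.321928	-2.321928	-2.321928	-2.321928	-2.321928	-2.321928	-2.321928	-2.321928	-2.321928	-2.321928	-2.321928	-2.321928	-2.321928	-2.321928	-2.321928	-2.321928	-2.321928	-2.321928	-2.321928	-2.321928	-2.321928	-2.321928	-2.321928	-2.321928	-2.321928	-2.321928	-2.321928	-2.321928	-2.321928	-2.321928
I	0.900464	-2.321928	-2.321928	-2.321928	-2.321928	0.900464	3.485427	-2.321928	-2.321928	0.900464	-2.321928	-2.321928	-2.321928	-2.321928	-2.321928	0.900464	-2.321928	-2.321928	-2.321928	3.485427	-2.321928	0.900464	-2.321928	-2.321928	-2.321928	0.900464	-2.321928	-2.321928	-2.321928	-2.321928	0.900464	-2.321928	-2.321928	-2.321928	0.900464
K	-2.321928	-2.321928	-2.321928	-2.321928	-2.321928	-2.321928	-2.321928	-2.321928	-2.321928	-2.321928	-2.321928	3.485427	-2.321928	-2.321928	3.485427	-2.321928	-2.321928	-2.321928	-2.321928	-2.321928	-2.321928	-2.321928	-2.321928	-2.321928	-2.321928	-2.321928	3.485427	-2.321928	3.485427	-2.321928	-2.321928	3.485427	-2.321928	-2.321928	-2.321928
L	0.900464	-2.321928	-2.321928	-2.321928	-2.321928	3.485427	0.900464	-2.321928	-2.321928	3.485427	-2.321928	-2.321928	-2.321928	-2.321928	-2.321928	3.485427	-2.321928	-2.321928	-2.321928	0.900464	-2.321928	3.485427	-2.321928	-2.321928	-2.321928	0.900464	-2.321928	-2.321928	-2.321928	-2.321928	0.900464	-2.321928	-2.321928	-2.321928	0.900464
M	0.900464	-2.321928	-2.321928	-2.321928	-2.321928	0.900464	0.900464	-2.321928	-2.321928	0.900464	-2.321928	-2.321928	-2.321928	-2.321928	-2.321928	0.900464	-2.321928	-2.321928	-2.321928	0.900464	-2.321928	0.900464	-2.321928	-2.321928	-2.321928	3.485427	-2.321928	-2.321928	-2.321928	-2.321928	0.900464	-2.321928	-2.321928	-2.321928	0.900464
N	-2.321928	-2.321928	-2.321928	3.485427	-2.321928	-2.321928	-2.321928	-2.321928	-2.321928	-2.321928	-2.321928	-2.321928	-2.321928	-2.321928	-2.321928	-2.321928	-2.321928	-2.321928	-2.321928	-2.321928	-2.321928	-2.321928	-2.321928	-2.321928	-2.321928	-2.321928	-2.321928	-2.321928	-2.321928	-2.321928	-2.321928	-2.321928	-2.321928	3.485427	-2.321928
P	-2.321928	-2.321928	-2.321928	-2.321928	-2.321928	-2.321928	-2.321928	-2.321928	-2.321928	-2.321928	-2.321928	-2.321928	-2.321928	-2.321928	-2.321928	-2.321928	-2.321928	-2.321928	-2.321928	-2.321928	-2.321928	-2.321928	-2.321928	-2.321928	-2.321928	-2.321928	-2.321928	-2.321928	-2.321928	-2.321928	-2.321928	-2.321928	4.017922	-2.321928	-2.321928
Q	-2.321928	-2.321928	-2.321928	2.378512	-2.321928	-2.321928	-2.321928	-2.321928	-2.321928	-2.321928	-2.321928	-2.321928	-2.321928	-2.321928	-2.321928	-2.321928	-2.321928	-2.321928	-2.321928	-2.321928	-2.321928	-2.321928	-2.321928	-2.321928	-2.321928	-2.321928	-2.321928	-2.321928	-2.321928	-2.321928	-2.321928	-2.321928	-2.321928	2.378512	-2.321928
R	-2.321928	-2.321928	-2.321928	-2.321928	-2.321928	-2.321928	-2.321928	-2.321928	-2.321928	-2.321928	-2.321928	2.378512	-2.321928	-2.321928	2.378512	-2.321928	-2.321928	-2.321928	-2.321928	-2.321928	-2.321928	-2.321928	-2.321928	-2.321928	-2.321928	-2.321928	2.378512	-2.321928	2.378512	-2.321928	-2.321928	2.378512	-2.321928	-2.321928	-2.321928
S	-2.321928	2.378512	-2.321928	-2.321928	2.378512	-2.321928	-2.321928	-2.321928	-2.321928	-2.321928	-2.321928	-2.321928	-2.321928	-2.321928	-2.321928	-2.321928	-2.321928	-2.321928	-2.321928	-2.321928	-2.321928	-2.321928	-2.321928	-2.321928	-2.321928	-2.321928	-2.321928	-2.321928	-2.321928	-2.321928	-2.321928	-2.321928	-2.321928	-2.321928	-2.321928
T	-2.321928	3.485427	-2.321928	-2.321928	3.485427	-2.321928	-2.321928	-2.321928	-2.321928	-2.321928	-2.321928	-2.321928	-2.321928	-2.321928	-2.321928	-2.321928	-2.321928	-2.321928	-2.321928	-2.321928	-2.321928	-2.321928	-2.321928	-2.321928	-2.321928	-2.321928	-2.321928	-2.321928	-2.321928	-2.321928	-2.321928	-2.321928	-2.321928	-2.321928	-2.321928
V	3.485427	-2.321928	-2.321928	-2.321928	-2.321928	0.900464	0.900464	-2.321928	-2.321928	0.900464	-2.321928	-2.321928	-2.321928	-2.321928	-2.321928	0.900464	-2.321928	-2.321928	-2.321928	0.900464	-2.321928	0.900464	-2.321928	-2.321928	-2.321928	0.900464	-2.321928	-2.321928	-2.321928	-2.321928	3.485427	-2.321928	-2.321928	-2.321928	3.485427
W	-2.321928	-2.321928	1.432959	-2.321928	-2.321928	-2.321928	-2.321928	-2.321928	-2.321928	-2.321928	-2.321928	-2.321928	-2.321928	-2.321928	-2.321928	-2.321928	-2.321928	-2.321928	-2.321928	-2.321928	-2.321928	-2.321928	1.432959	-2.321928	-2.321928	-2.321928	-2.321928	-2.321928	-2.321928	-2.321928	-2.321928	-2.321928	-2.321928	-2.321928	-2.321928
Y	-2.321928	-2.321928	3.485427	-2.321928	-2.321928	-2.321928	-2.321928	-2.321928	-2.321928	-2.321928	-2.321928	-2.321928	-2.321928	-2.321928	-2.321928	-2.321928	-2.321928	-2.321928	-2.321928	-2.321928	-2.321928	-2.321928	1.432959	-2.321928	-2.321928	-2.321928	-2.321928	-2.321928	-2.321928	-2.321928	-2.321928	-2.321928	-2.321928	-2.321928	-2.321928
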