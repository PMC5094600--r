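residue	mito	del	swinger_tri	swinger_tetra	swinger_penta	all
A	225	1	10	7	1	19
C	22	3	3	3	0	9
D	66	2	5	10	0	17
E	88	5	9	4	2	20
F	216	3	2	4	1	10
G	212	16	9	12	1	38
H	97	0	4	4	0	8
IL	963	19	6	19	46	90
K	95	18	22	22	11	73
M	208	8	9	6	5	28
N	164	8	7	5	3	23
P	219	5	3	9	5	22
Q	90	18	7	8	10	43
R	63	4	2	2	3	11
S	274	9	5	10	10	34
T	351	10	8	6	5	29
V	167	5	5	5	2	17
W	104	2	2	3	3	10
Y	135	2	1	7	4	14
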