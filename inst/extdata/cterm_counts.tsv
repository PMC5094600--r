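analysis	residue	detected	genome	rna_mapped
del	A	10	8328	0
del	C	4	5680	0
del	D	1	4662	0
del	E	6	6281	0
del	F	5	7868	0
del	G	12	12857	0
del	H	0	6578	0
del	IL	26	27890	3
del	K	16	8142	2
del	M	6	7581	0
del	N	5	7723	0
del	P	9	12857	3
del	Q	7	5647	2
del	R	9	5876	0
del	S	4	16856	1
del	T	3	11954	0
del	V	11	11954	2
del	W	9	6838	1
del	Y	5	7630	0
swinger_tri	A	2	46838	0
swinger_tri	C	0	22697	0
swinger_tri	D	3	21545	0
swinger_tri	E	4	24954	0
swinger_tri	F	4	30878	0
swinger_tri	G	9	57120	1
swinger_tri	H	4	22775	0
swinger_tri	IL	11	97382	0
swinger_tri	K	10	30603	0
swinger_tri	M	2	22553	0
swinger_tri	N	7	26449	0
swinger_tri	P	6	57489	0
swinger_tri	Q	6	24126	0
swinger_tri	R	11	46786	0
swinger_tri	S	5	68457	0
swinger_tri	T	9	46822	0
swinger_tri	V	10	46591	1
swinger_tri	W	3	23960	0
swinger_tri	Y	0	23238	0
swinger_tetra	A	6	47048	2
swinger_tetra	C	5	22836	0
swinger_tetra	D	0	21752	1
swinger_tetra	E	7	25290	0
swinger_tetra	F	4	30982	0
swinger_tetra	G	12	57648	0
swinger_tetra	H	7	22836	1
swinger_tetra	IL	15	97914	1
swinger_tetra	K	14	30982	0
swinger_tetra	M	4	22836	0
swinger_tetra	N	6	26660	0
swinger_tetra	P	7	57648	0
swinger_tetra	Q	13	24206	0
swinger_tetra	R	18	47048	0
swinger_tetra	S	2	68800	3
swinger_tetra	T	1	47047	0
swinger_tetra	V	4	47047	4
swinger_tetra	W	4	24206	0
swinger_tetra	Y	2	22836	0
swinger_penta	A	9	46178	0
swinger_penta	C	0	22108	0
swinger_penta	D	3	20795	0
swinger_penta	E	4	24200	0
swinger_penta	F	4	29626	1
swinger_penta	G	9	55452	0
swinger_penta	H	5	21803	0
swinger_penta	IL	6	93464	0
swinger_penta	K	14	29608	2
swinger_penta	M	4	21660	0
swinger_penta	N	5	25427	1
swinger_penta	P	7	55452	0
swinger_penta	Q	4	23422	0
swinger_penta	R	10	45626	0
swinger_penta	S	5	65983	0
swinger_penta	T	4	44813	0
swinger_penta	V	7	44813	1
swinger_penta	W	1	23118	0
swinger_penta	Y	4	21364	0
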