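analysis	residue	detected	genome
del	A	8	8328
del	C	4	5680
del	D	6	4662
del	E	6	6281
del	F	5	7868
del	G	13	12857
del	H	6	6578
del	IL	20	27890
del	K	5	8142
del	M	5	7581
del	N	9	7723
del	P	11	12857
del	Q	2	5647
del	R	3	5876
del	S	12	16856
del	T	11	11954
del	V	9	11954
del	W	7	6838
del	Y	6	7630
swinger_tri	A	6	46838
swinger_tri	C	3	22697
swinger_tri	D	3	21545
swinger_tri	E	8	24954
swinger_tri	F	2	30878
swinger_tri	G	8	57120
swinger_tri	H	4	22775
swinger_tri	IL	20	97382
swinger_tri	K	4	30603
swinger_tri	M	6	22553
swinger_tri	N	2	26449
swinger_tri	P	5	57489
swinger_tri	Q	4	24126
swinger_tri	R	8	46786
swinger_tri	S	8	68457
swinger_tri	T	12	46822
swinger_tri	V	13	46591
swinger_tri	W	2	23960
swinger_tri	Y	2	23238
swinger_tetra	A	10	47048
swinger_tetra	C	6	22836
swinger_tetra	D	7	21752
swinger_tetra	E	7	25290
swinger_tetra	F	5	30982
swinger_tetra	G	8	57648
swinger_tetra	H	4	22836
swinger_tetra	IL	25	97914
swinger_tetra	K	5	30982
swinger_tetra	M	5	22836
swinger_tetra	N	6	26660
swinger_tetra	P	12	57648
swinger_tetra	Q	4	24206
swinger_tetra	R	3	47048
swinger_tetra	S	19	68800
swinger_tetra	T	9	47047
swinger_tetra	V	5	47047
swinger_tetra	W	2	24206
swinger_tetra	Y	4	22836
swinger_penta	A	3	46178
swinger_penta	C	8	22108
swinger_penta	D	5	20795
swinger_penta	E	2	24200
swinger_penta	F	2	29626
swinger_penta	G	4	55452
swinger_penta	H	2	21803
swinger_penta	IL	18	93464
swinger_penta	K	4	29608
swinger_penta	M	4	21660
swinger_penta	N	3	25427
swinger_penta	P	11	55452
swinger_penta	Q	4	23422
swinger_penta	R	13	45626
swinger_penta	S	11	65983
swinger_penta	T	8	44813
swinger_penta	V	6	44813
swinger_penta	W	2	23118
swinger_penta	Y	2	21364
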