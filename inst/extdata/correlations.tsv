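analysis	split	r	n
del	tryptic	0.358	9
swinger_tri	tryptic	0.446	23
swinger_tetra	tryptic	0.109	23
swinger_penta	tryptic	0.192	23
del	other	0.27	9
swinger_tri	other	0.171	23
swinger_tetra	other	0.099	23
swinger_penta	other	0.306	23
del	all	0.401	9
swinger_tri	all	0.253	23
swinger_tetra	all	0.143	23
swinger_penta	all	0.186	23
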