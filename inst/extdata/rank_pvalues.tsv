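residue	analysis	p
K	del	0.0526315789473684
K	swinger_tri	0.0526315789473684
K	swinger_tetra	0.11
K	swinger_penta	0.0526315789473684
R	del	0.0555555555555556
R	swinger_tri	0.17
R	swinger_tetra	0.11
R	swinger_penta	0.11
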