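analysis	detected_total	genome_total	tryptic_detected	other_detected	tryptic_genome	other_genome	tryptic_mapped	tryptic_expected	other_mapped	other_expected
del	148	183202	25	123	14018	169184	2	1.07	12	5.24
swinger_tri	106	741263	21	85	77389	663874	0	0.68	2	2.34
swinger_tetra	127	745622	32	95	78030	667592	0	0.19	12	3.19
swinger_penta	105	714912	24	81	75234	639678	2	0.7	3	2.24
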