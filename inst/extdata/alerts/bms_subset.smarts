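# Representative BMS HTS-deck alerts (curated subset).
C(=O)OC(=O)	anhydride
C(=O)[Cl,Br]	acyl_halide
S(=O)(=O)[Cl,Br]	sulfonyl_halide
[CX4][N+](=O)[O-]	aliphatic_nitro
C(=O)C(=O)	alpha_dicarbonyl
[I]c	aryl_iodide
C=[N+]=[N-]	diazo
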