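# Representative Novartis NIBR deck alerts (curated subset).
[N+](C)(C)(C)C	quaternary_ammonium
C=CC=CC=C	extended_polyene
[Si]	silicon
[CH2][CH2][CH2][CH2][CH2][CH2][CH2][CH2]	long_alkyl_chain
O=C1OC(=O)c2ccccc21	phthalic_anhydride
N(=O)	nitroso_or_nitro
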