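# Representative Brenk structural alerts (curated subset).
[CX3H1]=O	aldehyde
N=C=O	isocyanate
N=C=S	isothiocyanate
C=CC(=O)[!O]	michael_acceptor_enone
[N+](=O)[O-]	nitro_group
[Cl,Br,I][CX4H2]	primary_alkyl_halide
[SH]	thiol
[NX3][NX3]	hydrazine
C1OC1	epoxide
N=[N+]=[N-]	azide
OO	peroxide
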