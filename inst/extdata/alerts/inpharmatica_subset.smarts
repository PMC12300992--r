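# Representative Inpharmatica alerts (curated subset).
[C;!R]=[C;!R][C;!R]=[C;!R]	acyclic_diene
C(=O)N(C(=O))C(=O)	triacylamine
S(=O)(=O)OS(=O)(=O)	disulfonate_ester
P(=O)(O)OP	pyrophosphate_like
[N+]#[C-]	isonitrile
SS	disulfide
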