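# Representative PAINS-family substructure alerts (curated subset).
# Format: SMARTS<TAB>name
O=C1CSC(=S)N1	rhodanine
O=C1CSC(=O)N1	thiazolidinone
O=C1C=CC(=O)C=C1	para_quinone
O=C1C(=O)c2ccccc21	ortho_quinone_indane
Oc1ccccc1O	catechol
Oc1ccc(O)cc1	hydroquinone
c1ccc(cc1)N=Nc1ccccc1	azo_aromatic
[OH]c1ccccc1C=N	hydroxyphenyl_imine
C(=S)N	thioamide
c1ccc2c(c1)C(=O)c1ccccc1C2=O	anthraquinone
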