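variant,conformer,populated,dG_kcal_mol
R5G42,2,TRUE,NA
R5G42,4,TRUE,NA
R5G42,7,TRUE,NA
R5G42,9,TRUE,NA
R5G42,13,TRUE,2.3
S35P,2,TRUE,NA
S35P,4,FALSE,NA
S35P,7,TRUE,NA
S35P,9,FALSE,NA
S35P,13,TRUE,1.2
F39I,2,FALSE,NA
F39I,4,TRUE,NA
F39I,7,FALSE,NA
F39I,9,TRUE,NA
F39I,13,TRUE,0.2
S35A,2,TRUE,NA
S35A,4,TRUE,NA
S35A,7,TRUE,NA
S35A,9,TRUE,NA
S35A,13,FALSE,NA
F39Y,2,TRUE,NA
F39Y,4,TRUE,NA
F39Y,7,TRUE,NA
F39Y,9,TRUE,NA
F39Y,13,FALSE,NA
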