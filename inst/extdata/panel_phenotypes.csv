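variant,CnA,NS5A-TP2
R5G42,binds,binds
S35P,binds,no_binding
F39I,binds,no_binding
S35A,no_binding,binds
F39Y,no_binding,binds
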