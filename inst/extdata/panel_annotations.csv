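variant,conformer,target,action,reason
F39I,4,NS5A-TP2,veto_exempt,loss of aromatic stacking at loop residue 39 explains the lost binding; the conformer itself is populated
F39I,9,NS5A-TP2,veto_exempt,loss of aromatic stacking at loop residue 39 explains the lost binding; the conformer itself is populated
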