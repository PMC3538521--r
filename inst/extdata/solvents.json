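["O", "CO", "CCO", "CC(C)O", "CS(C)=O", "CC(C)=O", "CC#N",
 "CN(C)C=O", "CCOCC", "C1CCOC1", "ClCCl", "ClC(Cl)Cl", "CCOC(C)=O"]
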