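["[Na+]", "[K+]", "[Li+]", "[Ca+2]", "[Mg+2]", "[NH4+]",
 "[Cl-]", "[Br-]", "[I-]", "[F-]", "Cl", "Br", "I",
 "CC(=O)[O-]", "[O-]S([O-])(=O)=O", "OS(O)(=O)=O", "[O-][N+](=O)[O-]",
 "O[N+]([O-])=O", "CS([O-])(=O)=O", "CS(O)(=O)=O",
 "Cc1ccc(cc1)S([O-])(=O)=O", "Cc1ccc(cc1)S(O)(=O)=O",
 "OC(=O)C(F)(F)F", "[O-]C(=O)C(F)(F)F", "OP(O)(O)=O", "OC(=O)C(O)C(O)C(=O)O"]
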