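# Linear aqueous-solubility surrogate: logS = c0 + c1*AlogP + c2*MW +
# c3*N_rot + c4*N_aromatic (ESOL-flavoured defaults; substitute published
# regression coefficients here if desired).
term,coefficient
intercept,0.16
AlogP,-0.63
MW,-0.0062
N_rot,0.066
N_aromatic,-0.020
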