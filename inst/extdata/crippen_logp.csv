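# Atom-contribution logP table (Crippen-style surrogate, condensed typing).
# Types are assigned by compute_logp(); contributions are additive.
type,contribution
C.sp3,0.1441
C.sp3.het,-0.2035
C.unsat,0.1001
C.carbonyl,-0.2051
C.ar,0.1511
C.ar.het,0.0521
H.C,0.1230
H.polar,-0.2677
N.amine,-0.7096
N.amide,-0.4806
N.sp2,-0.2500
N.ar,-0.3239
N.pos,-1.0190
O.hydroxyl,-0.3514
O.ether,-0.0684
O.carbonyl,-0.1188
O.ar,0.1552
O.neg,-1.1890
F,0.4202
Cl,0.6895
Br,0.8456
I,0.8857
S,0.6482
S.ar,0.6237
P,0.8612
wildcard,0.0000
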