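# Topological polar surface area fragment contributions (Angstrom^2) for
# nitrogen and oxygen environments, Ertl-style.
key,contribution
N.3single.H0,3.24
N.3single.H1,12.03
N.3single.H2,26.02
N.double.H0,12.36
N.double.H1,23.85
N.triple,23.79
N.nitro,11.68
N.ar.H0.deg2,12.89
N.ar.H0.deg3,4.41
N.ar.H1,15.79
N.pos.H0,0.00
N.pos.H1,4.44
N.pos.H2,16.61
N.pos.H3,27.64
N.ar.pos,4.10
O.single.H0,9.23
O.single.H1,20.23
O.double,17.07
O.ar,13.14
O.neg,23.06
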