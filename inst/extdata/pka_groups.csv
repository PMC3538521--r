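# Ionizable groups recognised by the logD7.4 surrogate and their default pKa.
group,kind,pka
carboxylic_acid,acid,4.5
sulfonic_acid,acid,-1.0
aliphatic_amine,base,10.5
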