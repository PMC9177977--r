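name,delta_formula,delta_mass
none,,0
acetyl,C2H2O,42.0105646859
formyl,CO,27.9949146221
Fmoc,C15H10O2,222.0680795632
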