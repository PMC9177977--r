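name,code,formula,monoisotopic_mass
Ala,A,C3H7NO2,89.0476784727
Arg,R,C6H14N4O2,174.1116757116
Asn,N,C4H8N2O3,132.0534921319
Asp,D,C4H7NO4,133.0375077169
Cys,C,C3H7NO2S,121.0197491627
Glu,E,C5H9NO4,147.0531577807
Gln,Q,C5H10N2O3,146.0691421957
Gly,G,C2H5NO2,75.0320284089
His,H,C6H9N3O2,155.0694765469
Ile,I,C6H13NO2,131.0946286641
Leu,L,C6H13NO2,131.0946286641
Lys,K,C6H14N2O2,146.1055277012
Met,M,C5H11NO2S,149.0510492903
Phe,F,C9H11NO2,165.0789786003
Pro,P,C5H9NO2,115.0633285365
Ser,S,C3H7NO3,105.0425930948
Thr,T,C4H9NO3,119.0582431586
Trp,W,C11H12N2O2,204.0898776374
Tyr,Y,C9H11NO3,181.0738932224
Val,V,C5H11NO2,117.0789786003
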