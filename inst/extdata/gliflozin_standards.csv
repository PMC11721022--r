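compound,name,logp_lit
S1,2-aminophenol,0.62
S2,salicylamide,1.28
S3,4-dimethylaminobenzaldehyde,1.81
S4,eugenol,2.27
S5,2-naphthol,2.70
S6,diphenylamine,3.5
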