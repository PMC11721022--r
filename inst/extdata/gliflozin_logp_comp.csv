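method,CANA,DAPA,EMPA,ERTU,SOTA
iLOGP,3.27,3.12,3.18,3.02,2.88
XLOGP3,3.23,2.35,2.03,1.71,3.23
WLOGP,3.06,1.52,1.29,1.25,2.85
MLOGP,1.95,1.07,0.70,0.89,1.88
SILICOS.IT,4.83,2.77,2.66,3.00,3.48
Consensus.LogP,3.26,2.18,1.97,1.97,2.86
ALOGP,3.09,2.52,1.79,2.22,3.19
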