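method,CANA,DAPA,EMPA,ERTU,SOTA
HPLC.CN.ACN,3.73,2.34,2.30,2.49,3.59
HPLC.CN.MeOH,4.91,3.08,2.66,3.36,4.57
HPLC.RP18.ACN,3.28,2.00,1.35,2.22,3.40
HPLC.RP18.MeOH,4.55,3.27,2.85,3.59,4.50
HPLC.RP8.ACN,3.23,2.11,1.70,2.40,3.28
HPLC.RP8.MeOH,4.43,3.20,2.78,3.49,4.43
TLC.CN.ACN,2.40,2.03,1.87,2.01,2.32
TLC.CN.MeOH,5.86,4.72,3.51,3.97,4.61
TLC.RP18.ACN,3.47,2.22,1.30,3.13,3.69
TLC.RP18.MeOH,4.43,3.58,2.99,3.27,4.50
TLC.RP8.ACN,3.55,2.30,1.68,2.99,4.08
TLC.RP8.MeOH,4.07,3.14,2.48,3.54,4.26
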