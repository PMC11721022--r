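method,technique,phase,modifier,slope_a,intercept_b
TLC.RP18.MeOH,TLC,RP18,methanol,1.118,-0.784
TLC.RP18.ACN,TLC,RP18,acetonitrile,1.647,-1.438
TLC.RP8.MeOH,TLC,RP8,methanol,1.501,-1.244
TLC.RP8.ACN,TLC,RP8,acetonitrile,1.950,-1.626
TLC.CN.MeOH,TLC,CN,methanol,2.619,-1.511
TLC.CN.ACN,TLC,CN,acetonitrile,1.138,-0.506
HPLC.RP18.MeOH,HPLC,RP18,methanol,1.071,0.264
HPLC.RP18.ACN,HPLC,RP18,acetonitrile,1.601,-0.449
HPLC.RP8.MeOH,HPLC,RP8,methanol,1.133,0.161
HPLC.RP8.ACN,HPLC,RP8,acetonitrile,1.360,-0.069
HPLC.CN.MeOH,HPLC,CN,methanol,2.642,-1.001
HPLC.CN.ACN,HPLC,CN,acetonitrile,2.521,-0.932
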