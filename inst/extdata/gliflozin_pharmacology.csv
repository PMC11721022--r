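drug,ic50_sglt2_nm,ic50_sglt1_nm,pb_percent,cl_l_per_h,vd_l,t05_h,dose_mg
CANA,2.2,910,99,11.52,83.5,10.6,100-300
SOTA,1.8,36,98,261,9392,21,200-400
ERTU,0.87,1960,94,10.68,85.5,11,5-15
DAPA,1.12,1390,91,12.42,118,12.9,5-50
EMPA,3.1,8300,86,10.6,73.8,12.4,10-25
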