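sex,age_group,D_d_cm,V_dn_ml_m2
female,total,4.6,68.5
female,20-29,4.7,67.2
female,30-39,4.9,73.2
female,40-49,4.4,63.7
female,50-59,4.2,58.0
female,60-69,4.5,61.3
male,total,4.9,74.2
male,20-29,5.0,78.1
male,30-39,5.1,74.9
male,40-49,5.1,73.9
male,50-59,4.8,68.9
male,60-69,4.6,66.6
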