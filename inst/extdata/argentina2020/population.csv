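sex,age_lo,age_hi,population
female,18,44,8400000
female,45,64,4300000
female,65,NA,2800000
male,18,44,8700000
male,45,64,4000000
male,65,NA,2000000
female,0,4,1800000
female,5,17,4500000
male,0,4,1900000
male,5,17,4700000
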