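sex,age_lo,age_hi,mean_servings,se_servings
female,18,44,1.1,0.11
female,45,64,0.8,0.08
female,65,NA,0.5,0.05
male,18,44,1.7,0.17
male,45,64,1.2,0.12
male,65,NA,0.6,0.06
female,0,4,0.7,0.07
female,5,17,1.6,0.16
male,0,4,0.7,0.07
male,5,17,1.9,0.19
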