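sex,age_lo,age_hi,mean_bmi,prev_overweight,prev_ob1,prev_ob2,prev_ob3
female,18,44,26.7,0.274,0.149,0.069,0.037
female,45,64,29.4,0.296,0.273,0.090,0.065
female,65,NA,29.8,0.339,0.263,0.108,0.063
male,18,44,26.9,0.355,0.171,0.056,0.020
male,45,64,29.5,0.427,0.279,0.096,0.026
male,65,NA,29.2,0.430,0.287,0.090,0.021
female,0,4,16.5,0.110,0.031,0,0
female,5,17,20.5,0.223,0.176,0,0
male,0,4,16.5,0.091,0.040,0,0
male,5,17,20.5,0.193,0.229,0,0
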