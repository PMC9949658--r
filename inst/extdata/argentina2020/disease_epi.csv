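disease,group,sex,incidence_rate,prevalence_rate,mortality_rate,disability_weight,cost_incident,cost_prevalent,events_basis
alzheimer_dementias,other,all,798,4311,483,0.15,0,1206,incident
asthma,asthma,all,251,4118,4.84,0.04,0,869,incident
atrial_fibrillation,cardiac,all,139,2462,63.11,0.08,573,1804,incident
ischemic_heart_disease,cardiac,all,835,3409,476,0.03,7613,1209,incident
chronic_kidney_disease,ckd,all,152,3019,21.15,0.04,0,869,incident
colorectal_cancer,other,all,101,283,82.01,0.06,8780,1146,incident
diabetes_t2,diabetes,all,356,12363,71.91,0.07,0,1414,prevalent
esophageal_cancer,other,all,16.39,14.20,16.16,0.20,13529,9163,incident
gallbladder_biliary_disease,other,all,245,1010,12.46,0,0,162,incident
gallbladder_biliary_cancer,other,all,20.04,12.13,19.62,0.28,10952,7497,incident
hypertensive_heart_disease,cardiac,all,812,1296,121,0.08,0,1058,incident
stroke,cerebrovascular,all,184,1371,133,0.15,0,1718,incident
subarachnoid_hemorrhage,cerebrovascular,all,36.33,234,17.28,0.15,0,3298,incident
kidney_cancer,other,all,24.40,99.26,13.92,0.07,11597,8122,incident
low_back_pain,musculoskeletal,all,6282,15901,0,0.11,0,10,prevalent
osteoarthritis,musculoskeletal,all,346,10592,0,0.03,0,223,prevalent
uterine_cancer,other,female,21.87,120,10.41,0.07,5492,543,incident
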