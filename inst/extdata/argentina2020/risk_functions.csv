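disease,pathway,outcome,rr_per_unit,ci_lo,ci_hi,reference_bmi
diabetes_t2,direct,all,1.37,1.16,1.58,NA
atrial_fibrillation,direct,incidence,1.08,1.04,1.13,NA
atrial_fibrillation,direct,mortality,1.08,1.02,1.14,NA
ischemic_heart_disease,direct,incidence,1.08,1.04,1.13,NA
ischemic_heart_disease,direct,mortality,1.08,1.02,1.14,NA
hypertensive_heart_disease,direct,incidence,1.08,1.04,1.13,NA
hypertensive_heart_disease,direct,mortality,1.08,1.02,1.14,NA
stroke,direct,incidence,1.08,1.04,1.13,NA
stroke,direct,mortality,1.08,1.02,1.14,NA
subarachnoid_hemorrhage,direct,incidence,1.08,1.04,1.13,NA
subarachnoid_hemorrhage,direct,mortality,1.08,1.02,1.14,NA
alzheimer_dementias,bmi_mediated,all,1.03,1.01,1.05,22.5
asthma,bmi_mediated,all,1.03,1.01,1.05,22.5
chronic_kidney_disease,bmi_mediated,all,1.06,1.03,1.09,22.5
colorectal_cancer,bmi_mediated,all,1.03,1.02,1.05,22.5
esophageal_cancer,bmi_mediated,all,1.05,1.02,1.08,22.5
gallbladder_biliary_disease,bmi_mediated,all,1.05,1.02,1.08,22.5
gallbladder_biliary_cancer,bmi_mediated,all,1.04,1.01,1.07,22.5
kidney_cancer,bmi_mediated,all,1.05,1.02,1.08,22.5
low_back_pain,bmi_mediated,all,1.03,1.01,1.05,22.5
osteoarthritis,bmi_mediated,all,1.04,1.02,1.06,22.5
uterine_cancer,bmi_mediated,all,1.08,1.04,1.12,22.5
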