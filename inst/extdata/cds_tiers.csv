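condition,score_1,score_2,score_3,score_weak_only
heart_disease,3,4,5,
hypertension,2,2,2,1
respiratory_illness,2,3,3,
cancer,3,3,3,
parkinsons_disease,3,3,3,
rheumatoid_arthritis,3,3,3,
epilepsy,2,2,2,
diabetes,2,2,2,
tuberculosis,2,2,2,
gout,1,2,2,
ulcers,1,2,2,
acne,1,1,1,
allergies,1,1,1,
glaucoma,1,1,1,
migraine,1,1,1,
thyroid_disorder,1,1,1,
high_cholesterol,1,1,1,
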