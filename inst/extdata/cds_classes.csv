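condition,ahfs_class,weak,label
heart_disease,20:12,0,anticoagulants and hemostatics
heart_disease,24:04,0,cardiac drugs
heart_disease,24:12,0,vasodilating agents (nitrates)
hypertension,24:08,0,hypotensive agents
hypertension,24:24,0,beta-adrenergic blocking agents
hypertension,24:28,0,calcium-channel blocking agents
hypertension,40:28,1,diuretics
respiratory_illness,12:12,0,adrenergic bronchodilators
respiratory_illness,86:16,0,respiratory smooth muscle relaxants (xanthines)
respiratory_illness,48:10,0,inhaled anti-inflammatory agents (cromolyn)
cancer,10:00,0,antineoplastic agents
parkinsons_disease,28:36,0,antiparkinsonian agents
rheumatoid_arthritis,60:00,0,gold compounds
rheumatoid_arthritis,92:36,0,disease-modifying antirheumatic agents
epilepsy,28:12,0,anticonvulsants
diabetes,68:20,0,antidiabetic agents
tuberculosis,08:16,0,antituberculosis agents
gout,92:16,0,antigout agents (colchicine)
gout,40:40,0,uricosuric agents
ulcers,56:28,0,antiulcer agents and acid suppressants
ulcers,56:40,0,misc GI drugs (sucralfate)
acne,84:28,0,keratolytic anti-acne agents
allergies,04:04,0,antihistamines
glaucoma,52:40,0,antiglaucoma agents
migraine,28:32,0,antimigraine agents (ergot derivatives)
thyroid_disorder,68:36,0,thyroid agents
high_cholesterol,24:06,0,antilipemic agents
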