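condition,system,pattern_type,pattern,weight,hierarchy_group,hierarchy_rank
diabetes_case,ICD9,prefix,250,,,
diabetes_case,ICD10,range,E10-E14,,,
osteoporosis,ICD9,prefix,733,,,
osteoporosis,ICD10,prefix,M80,,,
osteoporosis,ICD10,prefix,M81,,,
pagets_disease,ICD9,prefix,7310,,,
pagets_disease,ICD10,prefix,M880,,,
pagets_disease,ICD10,prefix,M888,,,
pagets_disease,ICD10,prefix,M889,,,
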