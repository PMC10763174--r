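item_id,category_id,category_label
s1,disease_interaction,Opioid-disease interaction
s2,population,Inappropriate for the population
s3,disease_interaction,Opioid-disease interaction
s4,disease_interaction,Opioid-disease interaction
s5,disease_interaction,Opioid-disease interaction
s6,disease_interaction,Opioid-disease interaction
s7,drug_interaction,Opioid-drug interaction
s8,disease_interaction,Opioid-disease interaction
s9,drug_interaction,Opioid-drug interaction
s10,drug_interaction,Opioid-drug interaction
s11,drug_interaction,Opioid-drug interaction
s12,disease_interaction,Opioid-disease interaction
s13,omission,Omission
s14,omission,Omission
s15,population,Inappropriate for the population
s16,dose,Inappropriate dose
s17,duration,Inappropriate duration
s18,population,Inappropriate for the population
s19,population,Inappropriate for the population
s20,disease_interaction,Opioid-disease interaction
s2m,population,Inappropriate for the population
s3m,disease_interaction,Opioid-disease interaction
s6m,disease_interaction,Opioid-disease interaction
s7m,drug_interaction,Opioid-drug interaction
s9m_ssri,drug_interaction,Opioid-drug interaction
s9m_maoi,drug_interaction,Opioid-drug interaction
s10m,drug_interaction,Opioid-drug interaction
s11m,drug_interaction,Opioid-drug interaction
s12m,disease_interaction,Opioid-disease interaction
s13m,omission,Omission
s16m,dose,Inappropriate dose
s17m,duration,Inappropriate duration
s19m,population,Inappropriate for the population
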