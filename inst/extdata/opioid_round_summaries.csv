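item_id,scenario,round,median,p30,p70,n_low,n_mid,n_high,di,label
s1,persistent opioid with substance misuse history,1,3,2,3,18,5,1,0.275,A/IA
s2,opioid during pregnancy,1,2,2,3,18,6,0,0.220,A/IA
s3,persistent opioid with hypothyroidism,1,5,4,7,7,10,7,0.658,Neutral
s4,persistent opioid with paralytic ileus,1,2,1,2,23,1,0,0.220,A/IA
s5,persistent opioid with dementia,1,3,2,4,16,7,1,0.299,A/IA
s6,persistent opioid with COPD or asthma,1,4,3,6,10,10,4,0.526,Neutral
s7,opioid with enzyme-inducing antiepileptics,1,4,3,6,9,11,4,0.502,Neutral
s8,persistent opioid with myasthenia gravis,1,4,3,5,11,10,3,0.458,Neutral
s9,opioid with antidepressants,1,5,4,6,7,13,4,0.539,Neutral
s10,opioid with a benzodiazepine,1,4,2,5,12,10,2,0.461,A/IA
s11,opioid with a gabapentinoid,1,5,3,5,11,10,3,0.564,Neutral
s12,opioid with galactose intolerance or lactase deficiency,1,5,5,6,5,13,6,0.549,Neutral
s13,opioid with constipation and no laxative,1,2,2,3,19,4,1,0.229,A/IA
s14,opioid 6 months or more with no laxative,1,2,2,3,18,5,1,0.220,A/IA
s15,codeine or morphine with severe renal impairment,1,1,2,4,13,8,3,0.120,A/IA
s16,opioid above 120 mg oral morphine equivalent per day,1,2,2,2,23,0,1,0.211,A/IA
s17,opioid beyond 3 months after surgical discharge,1,2,2,2,21,3,0,0.203,A/IA
s18,persistent opioid with moderate hepatic impairment,1,2,2,5,13,10,1,0.251,A/IA
s19,persistent opioid aged over 65 with falls history,1,2,2,4,16,8,0,0.240,A/IA
s20,tramadol buprenorphine or oxycodone with ventricular tachycardia,1,2,2,4,17,6,1,0.229,A/IA
s1,persistent opioid with substance misuse history,2,2,2,3,19,0,0,0.220,A/IA
s2,opioid during pregnancy,2,3,2,3,17,2,0,0.330,A/IA
s3,persistent opioid with hypothyroidism,2,5,4,6,4,12,3,0.599,Neutral
s4,persistent opioid with paralytic ileus,2,2,1,2,19,0,0,0.220,A/IA
s5,persistent opioid with dementia,2,2,2,3,15,4,0,0.220,A/IA
s6,persistent opioid with COPD or asthma,2,4,3,4,9,9,1,0.440,Neutral
s7,opioid with enzyme-inducing antiepileptics,2,3,3,5,10,8,1,0.359,A/IA
s8,persistent opioid with myasthenia gravis,2,3,2,4,10,7,2,0.359,A/IA
s9,opioid with antidepressants,2,4,3,5,6,11,2,0.479,Neutral
s10,opioid with a benzodiazepine,2,3,2,3,14,4,1,0.330,A/IA
s11,opioid with a gabapentinoid,2,4,3,4,9,10,0,0.440,Neutral
s12,opioid with galactose intolerance or lactase deficiency,2,5,3,5,6,13,0,0.599,Neutral
s13,opioid with constipation and no laxative,2,2,2,2,18,1,0,0.203,A/IA
s14,opioid 6 months or more with no laxative,2,2,2,2,17,2,0,0.203,A/IA
s15,codeine or morphine with severe renal impairment,2,2,2,2,17,2,0,0.203,A/IA
s16,opioid above 120 mg oral morphine equivalent per day,2,2,2,2,19,0,0,0.203,A/IA
s17,opioid beyond 3 months after surgical discharge,2,2,2,2,19,0,0,0.203,A/IA
s18,persistent opioid with moderate hepatic impairment,2,3,2,3,17,2,0,0.330,A/IA
s19,persistent opioid aged over 65 with falls history,2,2,2,2,18,1,0,0.203,A/IA
s20,tramadol buprenorphine or oxycodone with ventricular tachycardia,2,2,2,3,15,4,0,0.220,A/IA
s2m,persistent opioid during pregnancy (reworded),2,2,2,2,18,0,1,0.203,A/IA
s3m,persistent opioid with untreated hypothyroidism (reworded),2,4,2,4,9,8,2,0.479,Neutral
s6m,persistent opioid with severe COPD or asthma (reworded),2,3,2,3,14,5,0,0.330,A/IA
s7m,tramadol or tapentadol with enzyme-inducing antiepileptics (reworded),2,2,2,3,15,4,0,0.220,A/IA
s9m_ssri,serotonergic opioid with SSRI or SNRI (split),2,3,2,3,14,4,1,0.330,A/IA
s9m_maoi,serotonergic opioid with MAOI incl. 14-day washout (split),2,2,2,4,13,3,3,0.240,A/IA
s10m,persistent opioid with a benzodiazepine (reworded),2,2,2,3,17,1,1,0.220,A/IA
s11m,persistent opioid with a gabapentinoid (reworded),2,3,2,4,12,7,0,0.359,A/IA
s12m,opioid with galactose intolerance or lactase deficiency (reworded),2,5,5,5,5,14,0,0.508,Neutral
s13m,persistent opioid with no laxative (reworded),2,2,2,3,14,5,0,0.220,A/IA
s16m,opioid above 120 mg total morphine equivalent load per day (reworded),2,2,2,2,19,0,0,0.203,A/IA
s17m,persistent opioid after surgical discharge (reworded),2,2,2,2,19,0,0,0.203,A/IA
s19m,persistent opioid aged over 65 with falls history (reworded),2,2,2,3,17,2,0,0.220,A/IA
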