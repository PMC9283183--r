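member_id,sex,birth_year,region,payer,plan_type
M1,F,1948,South,Commercial,PPO
M2,F,1955,Midwest,Commercial,HMO
M3,F,1960,West,MedicareRisk,PPO
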