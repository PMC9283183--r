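member_id,fill_date,drug_code,days_supply
M1,2016-05-01,RX_OBP_1,30
M1,2016-06-01,RX_OBP_1,30
M2,2016-09-01,RX_DENO_1,90
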