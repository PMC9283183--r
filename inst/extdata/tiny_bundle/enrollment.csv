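member_id,start_date,end_date,medical,pharmacy
M1,2014-06-01,2019-12-31,TRUE,TRUE
M2,2015-01-01,2018-06-30,TRUE,TRUE
M3,2014-01-01,2019-12-31,TRUE,TRUE
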