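member_id,service_date,setting,dx_codes,proc_codes,admission_date,discharge_date
M1,2016-03-10,inpatient,FXDX_HIP_1,,2016-03-10,2016-03-14
M1,2016-04-20,outpatient,,REHAB_PT_1,,
M2,2016-07-01,outpatient,FXDX_VER_1,EM_1,,
M2,2016-08-15,outpatient,,DXA_1,,
M3,2017-02-01,outpatient,FXDX_RAD_1,,,
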