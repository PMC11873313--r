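trial_id,participant,device,n_back,trial_type,rt_ms,accuracy
vr_m_1,p01,vr,1,match,650,1
vr_nm_1,p01,vr,1,nonmatch,850,1
cl_m_1,p01,classical,1,match,540,1
cl_nm_1,p01,classical,1,nonmatch,760,0
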