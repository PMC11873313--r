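trial_id,t_ms,x_m
vr_m_1,0,0
vr_m_1,100,0.005
vr_m_1,200,0.03
vr_m_1,300,0.07
vr_m_1,400,0.11
vr_m_1,500,0.155
vr_m_1,600,0.19
vr_m_1,650,0.2
vr_nm_1,0,0
vr_nm_1,100,-0.002
vr_nm_1,200,0.02
vr_nm_1,300,-0.01
vr_nm_1,400,-0.06
vr_nm_1,500,-0.1
vr_nm_1,600,-0.14
vr_nm_1,700,-0.175
vr_nm_1,800,-0.195
vr_nm_1,850,-0.2
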