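patient_id,phq9_baseline,n_cbt_sessions,n_cfd_sessions,n_other_hit_sessions,n_appointments,referral_number,year,phq9_post
P001,18,5,0,0,6,1,2018,9
P002,12,0,4,1,5,1,2017,11
P003,10,3,0,0,4,1,2019,8
P004,22,0,6,2,7,2,2018,15
P005,16,4,1,0,5,2,2019,12
P006,8,3,0,0,4,1,2018,7
P007,14,3,3,0,6,1,2018,10
P008,17,1,0,0,1,1,2018,13
P005,15,3,0,0,4,1,2017,10
P009,19,5,0,0,6,1,2019,
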