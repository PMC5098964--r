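subject,age_y,sex,body_mass_kg,shoulder_height_m,rff_circumference_m,rhf_circumference_m,froude,velocity_ms,mpp_fore_left_kpa,mpp_fore_left_se,mpp_fore_right_kpa,mpp_fore_right_se,mpp_hind_left_kpa,mpp_hind_left_se,mpp_hind_right_kpa,mpp_hind_right_se,n_steps,n_trials
1,15,M,2800,2.43,1.21,1.18,0.07,1.24,317,68,296,24,237,16,244,18,28,13
2,18,M,3000,2.50,1.27,1.24,0.05,1.11,251,23,312,29,250,10,248,12,29,18
3,11,F,1500,2.22,1.06,1.07,0.07,1.24,256,10,236,10,243,12,251,13,76,30
4,12,F,1800,2.12,1.06,1.10,0.08,1.24,262,16,224,10,200,11,235,14,48,23
5,13,F,2300,2.30,1.08,1.08,0.08,1.34,315,19,318,21,297,27,284,44,29,10
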