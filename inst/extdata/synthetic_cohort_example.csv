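patient_id,age_years,sex,weight_kg,height_m,bmi,hba1c_pct,on_treatment,diabetes_duration_years,on_insulin,on_oral_meds,co_htn,co_dyslip,co_nash,co_albuminuria,co_joint,co_repro,co_renal,co_osa,pe_risk,asa_class,indigenous,months,weight_kg_12m,hba1c_pct_12m,on_insulin_12m,on_oral_meds_12m,aqol_pre,aqol_12m,co_htn_12m,co_dyslip_12m,co_nash_12m,co_albuminuria_12m,co_joint_12m,co_repro_12m,co_renal_12m,co_osa_12m,ae_list,score
P0001,63.9,female,109.2,1.65,40.1,9.73,1,6,0,1,1,1,0,0,1,0,0,1,0,3,0,12,84.5,4.7,0,0,0.632,0.515,i,r,,,u,,,i,,47
P0002,47.1,male,164,1.88,46.4,8.9,1,19.3,1,1,1,1,0,0,1,0,1,0,0,3,0,12,149.5,5,0,0,0.993,0.676,i,i,,,i,,i,,,46
P0003,55.2,female,155.6,1.81,47.5,9.18,1,12,1,1,1,1,0,0,1,0,0,1,0,2,1,12,126.6,9.1,0,0,0.465,0.233,r,r,,,r,,,i,,38
P0004,57.5,male,133.5,1.75,43.6,9.79,1,10.3,0,1,1,1,0,0,0,0,0,1,1,2,0,12,97.2,8.69,0,1,0.35,0.574,i,r,,,,,,u,,21
P0005,55.5,female,138.2,1.64,51.4,8.9,1,5.1,1,1,1,1,1,0,1,1,0,1,0,2,0,12,117.7,6.53,0,0,0.686,0.624,i,r,i,,r,r,,i,,59
P0006,51.1,female,94.7,1.52,41,9.2,1,14.4,1,1,1,1,0,0,1,0,0,1,1,2,1,12,75.3,7.67,0,1,0.374,0.598,r,r,,,u,,,i,other;wound_infection,35
P0007,51.2,male,120.9,1.82,36.5,8.22,1,0.6,0,1,1,1,0,0,1,0,0,1,0,2,1,12,88.9,5.4,0,1,0.682,0.825,i,r,,,r,,,r,,45
P0008,51.5,male,147,1.73,49.1,9.05,1,7.2,1,1,0,1,0,0,1,0,0,1,0,2,0,12,114,6.95,1,1,0.649,0.83,,r,,,r,,,u,wound_infection,48
P0009,63.4,female,116.8,1.7,40.4,9.64,1,9.3,0,1,1,0,0,0,1,0,0,1,0,1,0,12,97.1,8,0,1,0.504,0.616,u,,,,i,,,r,,33
P0010,39.9,female,166.3,1.72,56.2,10.87,1,2.4,0,1,1,1,0,0,1,0,0,1,0,1,0,12,156.6,5.44,0,0,0.445,0.747,r,i,,,i,,,u,,70
P0011,49.6,female,130.5,1.74,43.1,7.68,1,2.5,1,1,1,1,0,0,0,0,0,0,0,2,0,12,79.3,5.51,1,0,0.568,0.925,u,i,,,,,,,,54
P0012,50.8,male,151.7,1.73,50.7,10.72,1,6.5,0,1,1,1,0,0,0,0,0,0,1,2,0,12,130,10.82,0,1,0.628,0.337,r,i,,,,,,,,31
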