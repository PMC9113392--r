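# pedtriage-visit-table v1
"visit_id","age_days","age_band","sex","critical_flag","items","risk_conditions","glasgow","heart_rate","resp_rate","spo2","oxygen_support","pews_behavior","pews_cardiovascular","pews_respiratory","outcome","los_minutes","complaint_category","complaint_type","diagnosis","intended_level","intended_acuity","psychiatric","left_without_being_seen","unreliable_vitals"
"V0000001",2603,"7-12y","female",FALSE,"rheumatology_pain/L2","",,,,,,2,0,0,"discharged",113.7,"rheumatology_pain","medical","fever",2,"low",FALSE,FALSE,FALSE
"V0000002",5760,"12-18y","female",FALSE,"trunk_pelvis_urogenital_trauma/L3;trunk_pelvis_urogenital_trauma/L5","",15,63,14,96,,0,1,0,"discharged",113.8,"trunk_pelvis_urogenital_trauma","surgical","acute_gastroenteritis",3,"low",TRUE,FALSE,FALSE
"V0000003",290,"3m-1y","male",FALSE,"upper_limb_trauma/L4;upper_limb_trauma/L5","",,,,,,3,0,0,"discharged",133.7,"upper_limb_trauma","surgical","other",4,"low",FALSE,FALSE,FALSE
"V0000004",444,"1-3y","male",FALSE,"upper_limb_trauma/L4;upper_limb_trauma/L5","",,,,,,1,1,0,"discharged",12.1,"upper_limb_trauma","surgical","acute_gastroenteritis",4,"low",FALSE,FALSE,FALSE
"V0000005",588,"1-3y","female",FALSE,"neurology/L3","",,,,,,0,0,1,"discharged",62.8,"neurology","medical","other",3,"low",FALSE,FALSE,FALSE
"V0000006",20,"0-28d","female",FALSE,"pulmonary/L2;pulmonary/L4","",15,135,43,97,,0,0,0,"discharged",164.9,"pulmonary","medical","bronchiolitis",2,"low",FALSE,TRUE,FALSE
"V0000007",3425,"7-12y","female",FALSE,"digestive/L4","",,,,,,1,0,2,"discharged",186,"digestive","medical","lower_limb_trauma",4,"low",FALSE,FALSE,FALSE
"V0000008",2616,"7-12y","male",FALSE,"dermatology/L5","",,,,,,0,0,0,"discharged",24.8,"dermatology","medical","other",5,"low",FALSE,FALSE,FALSE
"V0000009",2089,"3-7y","male",FALSE,"digestive/L3","",15,110,26,98,,0,0,0,,39.6,"digestive","medical","mild_traumatic_brain_injury",3,"low",FALSE,FALSE,FALSE
"V0000010",1008,"1-3y","male",FALSE,"lower_limb_trauma/L4","",,,,,,0,0,0,"discharged",163.3,"lower_limb_trauma","surgical","lower_limb_trauma",4,"low",FALSE,FALSE,FALSE
"V0000011",4075,"7-12y","female",FALSE,"lower_limb_trauma/L4","",,,,,,0,0,0,"discharged",73.6,"lower_limb_trauma","surgical","ent_infection",4,"low",FALSE,FALSE,FALSE
"V0000012",6406,"12-18y","male",FALSE,"rheumatology_pain/L2","",,,,,,0,3,0,"hospitalization",98.7,"rheumatology_pain","medical","other",2,"low",FALSE,FALSE,FALSE
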