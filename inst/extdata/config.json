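{"demographics":{"baseline_age":57.5,"cohort_size":1000,"male_fraction":0.65000000000000002,"baseline_cha2ds2vasc":1,"initial_af_fraction":1},"settings":{"cycle_length":0.25,"horizon":40,"tree_horizon":1,"discount_rate_costs":0.029999999999999999,"discount_rate_effects":0.029999999999999999,"wtp":35000,"max_total_ablations":3,"blanking_period_active":false,"half_cycle_correction":false},"costs":{"ablation_procedure":8121,"cv_hospitalization":1464,"ed_visit":32,"outpatient":107,"pharm_cardioversion":1206,"elec_cardioversion":166,"stroke_acute":{"non_disabling":1204,"moderate":2864,"severe":5168},"stroke_longterm_per_cycle":391,"hf_per_cycle":{"nyha1":166,"nyha2":213,"nyha3":244,"nyha4":291},"pharma_per_cycle":{"cryoablation":69,"aad":89}},"utilities":{"norm_at_ref":{"male":0.89300000000000002,"female":0.876},"norm_ref_age":57.5,"norm_slope_per_year":0.0035000000000000001,"norm_floor":0.40000000000000002,"decrement_st_episodic":0.080000000000000002,"decrement_lt_persistent":0.080000000000000002,"decrement_permanent":0.11,"stroke_short_decrement":{"non_disabling":0,"moderate":0.23000000000000001,"severe":0.59999999999999998},"stroke_long_decrement":{"non_disabling":0,"moderate":0.17000000000000001,"severe":0.34999999999999998},"hf_decrement":{"nyha1":0,"nyha2":0.050000000000000003,"nyha3":0.14999999999999999,"nyha4":0.33000000000000002}},"risks":{"recurrence":{"cryoablation":0.036289954537850333,"aad":0.065000000000000002},"resolution":{"cryoablation":0.25,"aad":0.22},"progression_st_lt":0.01,"progression_lt_perm":0.040000000000000001,"remission_lt_st":0,"reablation":{"cryoablation":{"st":0.029999999999999999,"lt":0.014999999999999999},"aad":{"st":0.070000000000000007,"lt":0.035000000000000003}},"rr_recurrence_by_count":[1,0.84999999999999998,0.80000000000000004,0.75],"rr_resolution_by_count":[1,1.1000000000000001,1.1499999999999999,1.2],"ablation_success":0.80000000000000004,"stroke":{"annual_incidence_by_score":[0.002,0.0060000000000000001,0.012,0.02,0.029999999999999999,0.042000000000000003,0.056000000000000001,0.071999999999999995,0.089999999999999997,0.11],"rr_by_state":{"nsr":1,"st":1.2,"lt":1.3999999999999999,"permanent":1.6000000000000001},"rr_by_state_literature":{"nsr":1,"st":1.05,"lt":1.1000000000000001,"permanent":1.1499999999999999},"severity_split":{"non_disabling":0.5,"moderate":0.29999999999999999,"severe":0.20000000000000001},"case_fatality":0.14999999999999999},"hf":{"age_band_lower":[0,60,70,80,90],"annual_incidence":[0.002,0.0040000000000000001,0.0089999999999999993,0.017999999999999999,0.035000000000000003],"rr_permanent":1.5,"nyha_split":{"nyha1":0.25,"nyha2":0.40000000000000002,"nyha3":0.25,"nyha4":0.10000000000000001},"excess_annual_mortality":0.10000000000000001},"utilization":{"hospitalization":{"cryoablation":{"nsr":0.002,"st":0.025000000000000001,"lt":0.035000000000000003,"permanent":0.029999999999999999},"aad":{"nsr":0.002,"st":0.025000000000000001,"lt":0.035000000000000003,"permanent":0.029999999999999999}},"ed_visit":{"cryoablation":{"nsr":0.002,"st":0.029999999999999999,"lt":0.040000000000000001,"permanent":0.029999999999999999},"aad":{"nsr":0.002,"st":0.029999999999999999,"lt":0.040000000000000001,"permanent":0.029999999999999999}},"outpatient":{"cryoablation":{"nsr":0.050000000000000003,"st":0.29999999999999999,"lt":0.40000000000000002,"permanent":0.29999999999999999},"aad":{"nsr":0.050000000000000003,"st":0.29999999999999999,"lt":0.40000000000000002,"permanent":0.29999999999999999}},"pharm_cardioversion":{"cryoablation":{"nsr":0,"st":0.01,"lt":0.01,"permanent":0},"aad":{"nsr":0,"st":0.01,"lt":0.01,"permanent":0}},"elec_cardioversion":{"cryoablation":{"nsr":0,"st":0.014999999999999999,"lt":0.014999999999999999,"permanent":0},"aad":{"nsr":0,"st":0.014999999999999999,"lt":0.014999999999999999,"permanent":0}}}},"psa":{"n_iterations":5000,"expert_se_fraction":0.10000000000000001,"coefficient_block":{"chol":[[0.10601758490483305,0,0,0],[0.022944513221439106,0.072958902064533912,0,0],[0.019329396013927778,0.014183898921075504,0.059804568922937937,0],[0.027182203967061919,0.019946284573147365,0.015768922527256275,0.082609356925391647]],"scale":1,"labels":["recurrence.cryoablation","recurrence.aad","resolution.cryoablation","resolution.aad"]}},"life_table":"life_table.csv","meta":{"placeholders":["demographics.male_fraction","demographics.initial_af_fraction","utilities.norm_at_ref","utilities.norm_slope_per_year","risks.recurrence","risks.resolution","risks.progression_st_lt","risks.progression_lt_perm","risks.reablation","risks.rr_recurrence_by_count","risks.rr_resolution_by_count","risks.ablation_success","risks.stroke.annual_incidence_by_score","risks.stroke.rr_by_state","risks.stroke.rr_by_state_literature","risks.stroke.severity_split","risks.stroke.case_fatality","risks.hf","risks.utilization","life_table"]}}
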