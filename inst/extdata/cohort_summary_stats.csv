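variable,mean_case,sd_case,mean_control,sd_control,n_case,n_control
current_inattentive_symptoms,6.12,2.00,0.07,0.25,74,74
current_hyperactive_impulsive_symptoms,4.51,2.27,0.08,0.28,74,74
current_total_adhd_symptoms,10.64,3.33,0.15,0.39,74,74
bsi_general_severity_index,1.30,0.67,0.17,0.14,74,74
omission_errors_go,4.36,4.93,1.23,1.71,74,74
rt_go_ms,420.41,83.81,419.42,94.06,74,74
standard_error_mean_rt_ms,11.03,3.83,8.20,2.55,74,74
commission_errors_nogo,0.64,1.02,0.45,0.80,74,74
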