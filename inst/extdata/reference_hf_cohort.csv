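quantity,value
original_cohort_n,502723
rejected_patients_n,356
cdm_cohort_n,502367
primary_care_visits_n,211209045
hospital_visits_n,5372869
total_visits_n,216581914
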