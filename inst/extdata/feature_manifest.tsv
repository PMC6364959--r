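name	kind	source
gender_male	binary	demographics
race_white	binary	demographics
race_black	binary	demographics
race_hispanic	binary	demographics
race_asian	binary	demographics
race_other	binary	demographics
marital_married	binary	demographics
insurance_private	binary	demographics
insurance_medicaid	binary	demographics
insurance_medicare	binary	demographics
insurance_other	binary	demographics
age	continuous	demographics
bmi	continuous	clinical
charlson_3plus	binary	diagnoses
sbp_deviation	continuous	vitals
dbp_deviation	continuous	vitals
temp_deviation	continuous	vitals
hr_normal	binary	vitals
hr_abnormal	binary	vitals
hr_unknown	binary	vitals
preop_pain	continuous	clinical
preop_pain_missing	binary	clinical
opioid_tolerant	binary	medications
daily_ome	continuous	medications
surgery_orthopedic	binary	procedures
surgery_vascular	binary	procedures
surgery_general	binary	procedures
surgery_cardiothoracic	binary	procedures
surgery_neurosurgery	binary	procedures
surgery_urology	binary	procedures
surgery_gynecology	binary	procedures
surgery_ent	binary	procedures
surgery_plastic	binary	procedures
surgery_other	binary	procedures
group_ssri_pro	binary	cohort
group_ssri_nonpro	binary	cohort
group_nossri_pro	binary	cohort
group_nossri_nonpro	binary	cohort
med_opioid	binary	medications
med_antidepressant_other	binary	medications
med_nsaid	binary	medications
med_analgesic_other	binary	medications
med_gabapentinoid	binary	medications
med_benzodiazepine	binary	medications
med_sleep_aid	binary	medications
med_antipsychotic	binary	medications
med_anticonvulsant	binary	medications
med_statin	binary	medications
med_beta_blocker	binary	medications
med_ace_inhibitor	binary	medications
med_arb	binary	medications
med_calcium_channel_blocker	binary	medications
med_diuretic	binary	medications
med_anticoagulant	binary	medications
med_antiplatelet	binary	medications
med_insulin	binary	medications
med_oral_hypoglycemic	binary	medications
med_ppi	binary	medications
med_corticosteroid	binary	medications
med_antibiotic	binary	medications
med_antihistamine	binary	medications
med_bronchodilator	binary	medications
med_thyroid	binary	medications
med_muscle_relaxant	binary	medications
med_antiemetic	binary	medications
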