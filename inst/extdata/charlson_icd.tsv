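condition	family	weight	icd9_prefix	icd10_prefix
myocardial_infarction	mi	1	410;412	I21;I22;I252
congestive_heart_failure	chf	1	428	I50
peripheral_vascular	pvd	1	441;4439;7854	I70;I71;I731
cerebrovascular	cvd	1	430;431;432;433;434;435;436;437;438	I60;I61;I62;I63;I64;I65;I66;I67;I69;G45
dementia	dementia	1	290	F00;F01;F02;F03;G30
chronic_pulmonary	copd	1	490;491;492;493;494;495;496	J40;J41;J42;J43;J44;J45;J47
rheumatologic	rheum	1	7100;7101;7104;714	M05;M06;M32;M34
peptic_ulcer	pud	1	531;532;533;534	K25;K26;K27;K28
mild_liver_disease	liver	1	5712;5714;5715;5716	K70;K73;K74
diabetes	diabetes	1	2500;2501;2502;2503	E109;E119;E139
diabetes_complicated	diabetes	2	2504;2505;2506;2507	E102;E112;E132
hemiplegia	hemi	2	342;3441	G81;G82
renal_disease	renal	2	582;583;585;586;V420	N18;N19;Z940
any_malignancy	cancer	2	14;15;16;17;18;19;200;201;202;203;204;205;206;207;208	C18;C34;C50;C61;C64;C81;C82;C85;C91;C92
moderate_severe_liver	liver	3	5722;5723;5724	K721;K729;I85
metastatic_solid_tumor	cancer	6	196;197;198;199	C77;C78;C79;C80
aids	aids	6	042;043;044	B20;B21;B22;B24
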