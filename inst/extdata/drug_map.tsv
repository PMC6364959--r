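name	ingredients	class
vicodin	hydrocodone;acetaminophen	opioid
norco	hydrocodone;acetaminophen	opioid
lortab	hydrocodone;acetaminophen	opioid
hydrocodone-acetaminophen	hydrocodone;acetaminophen	opioid
hydrocodone bitartrate	hydrocodone	opioid
hydrocodone	hydrocodone	opioid
codeine sulfate	codeine	opioid
codeine	codeine	opioid
tylenol with codeine no. 3	codeine;acetaminophen	opioid
tramadol hcl	tramadol	opioid
tramadol	tramadol	opioid
ultram	tramadol	opioid
ultracet	tramadol;acetaminophen	opioid
morphine sulfate	morphine	opioid
morphine	morphine	opioid
ms contin	morphine	opioid
oxycodone hcl	oxycodone	opioid
oxycodone	oxycodone	opioid
oxycontin	oxycodone	opioid
roxicodone	oxycodone	opioid
percocet	oxycodone;acetaminophen	opioid
endocet	oxycodone;acetaminophen	opioid
fentanyl	fentanyl	opioid
fentanyl transdermal system	fentanyl	opioid
duragesic	fentanyl	opioid
hydromorphone hcl	hydromorphone	opioid
hydromorphone	hydromorphone	opioid
dilaudid	hydromorphone	opioid
methadone hcl	methadone	opioid
methadone	methadone	opioid
dolophine	methadone	opioid
sertraline	sertraline	ssri
zoloft	sertraline	ssri
fluoxetine	fluoxetine	ssri
prozac	fluoxetine	ssri
citalopram	citalopram	ssri
celexa	citalopram	ssri
escitalopram	escitalopram	ssri
lexapro	escitalopram	ssri
paroxetine	paroxetine	ssri
paxil	paroxetine	ssri
fluvoxamine	fluvoxamine	ssri
luvox	fluvoxamine	ssri
amitriptyline	amitriptyline	antidepressant_other
bupropion	bupropion	antidepressant_other
wellbutrin	bupropion	antidepressant_other
venlafaxine	venlafaxine	antidepressant_other
duloxetine	duloxetine	antidepressant_other
cymbalta	duloxetine	antidepressant_other
mirtazapine	mirtazapine	antidepressant_other
ibuprofen	ibuprofen	nsaid
motrin	ibuprofen	nsaid
naproxen	naproxen	nsaid
aleve	naproxen	nsaid
celecoxib	celecoxib	nsaid
celebrex	celecoxib	nsaid
ketorolac	ketorolac	nsaid
acetaminophen	acetaminophen	analgesic_other
tylenol	acetaminophen	analgesic_other
gabapentin	gabapentin	gabapentinoid
neurontin	gabapentin	gabapentinoid
pregabalin	pregabalin	gabapentinoid
lyrica	pregabalin	gabapentinoid
lorazepam	lorazepam	benzodiazepine
ativan	lorazepam	benzodiazepine
alprazolam	alprazolam	benzodiazepine
xanax	alprazolam	benzodiazepine
diazepam	diazepam	benzodiazepine
valium	diazepam	benzodiazepine
clonazepam	clonazepam	benzodiazepine
zolpidem	zolpidem	sleep_aid
ambien	zolpidem	sleep_aid
quetiapine	quetiapine	antipsychotic
seroquel	quetiapine	antipsychotic
risperidone	risperidone	antipsychotic
levetiracetam	levetiracetam	anticonvulsant
keppra	levetiracetam	anticonvulsant
lamotrigine	lamotrigine	anticonvulsant
topiramate	topiramate	anticonvulsant
atorvastatin	atorvastatin	statin
lipitor	atorvastatin	statin
simvastatin	simvastatin	statin
rosuvastatin	rosuvastatin	statin
metoprolol	metoprolol	beta_blocker
atenolol	atenolol	beta_blocker
carvedilol	carvedilol	beta_blocker
lisinopril	lisinopril	ace_inhibitor
enalapril	enalapril	ace_inhibitor
losartan	losartan	arb
valsartan	valsartan	arb
amlodipine	amlodipine	calcium_channel_blocker
diltiazem	diltiazem	calcium_channel_blocker
furosemide	furosemide	diuretic
lasix	furosemide	diuretic
hydrochlorothiazide	hydrochlorothiazide	diuretic
warfarin	warfarin	anticoagulant
coumadin	warfarin	anticoagulant
apixaban	apixaban	anticoagulant
eliquis	apixaban	anticoagulant
enoxaparin	enoxaparin	anticoagulant
aspirin	aspirin	antiplatelet
clopidogrel	clopidogrel	antiplatelet
plavix	clopidogrel	antiplatelet
insulin glargine	insulin	insulin
lantus	insulin	insulin
insulin lispro	insulin	insulin
metformin	metformin	oral_hypoglycemic
glucophage	metformin	oral_hypoglycemic
glipizide	glipizide	oral_hypoglycemic
omeprazole	omeprazole	ppi
prilosec	omeprazole	ppi
pantoprazole	pantoprazole	ppi
protonix	pantoprazole	ppi
prednisone	prednisone	corticosteroid
dexamethasone	dexamethasone	corticosteroid
cephalexin	cephalexin	antibiotic
keflex	cephalexin	antibiotic
amoxicillin	amoxicillin	antibiotic
ciprofloxacin	ciprofloxacin	antibiotic
diphenhydramine	diphenhydramine	antihistamine
benadryl	diphenhydramine	antihistamine
loratadine	loratadine	antihistamine
albuterol	albuterol	bronchodilator
ventolin	albuterol	bronchodilator
tiotropium	tiotropium	bronchodilator
levothyroxine	levothyroxine	thyroid
synthroid	levothyroxine	thyroid
cyclobenzaprine	cyclobenzaprine	muscle_relaxant
flexeril	cyclobenzaprine	muscle_relaxant
methocarbamol	methocarbamol	muscle_relaxant
ondansetron	ondansetron	antiemetic
zofran	ondansetron	antiemetic
promethazine	promethazine	antiemetic
docusate	docusate	laxative
colace	docusate	laxative
senna	senna	laxative
sumatriptan	sumatriptan	triptan
imitrex	sumatriptan	triptan
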