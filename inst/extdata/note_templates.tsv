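category	text
affirmed	major depressive disorder, recurrent episode, moderate.
affirmed	stress and depression, need to continue medication.
affirmed	patient stating more depression recently, was at behavioral facility.
affirmed	patient reports ongoing depression and poor sleep.
affirmed	history of depression, currently followed by psychiatry.
affirmed	screening positive for depressive symptoms today.
affirmed	assessment includes depression, stable on current regimen.
affirmed	continues to struggle with low mood and anhedonia.
affirmed	chronic depression with intermittent hopelessness reported.
affirmed	patient endorses depressed mood most days.
negated	patient had no preinjury mental health issues or depression.
negated	anxiety was situational, currently no symptoms of depression.
negated	denies depression, anxiety, or suicidal thoughts.
negated	no history of depression or other psychiatric illness.
negated	negative for depression on routine screening.
negated	patient denies depressive symptoms at this visit.
negated	screening shows no evidence of depression today.
decoy	ecg shows st depression in leads ii and iii.
decoy	st segment depression noted on stress testing.
decoy	ct head shows depressed skull fracture without midline shift.
decoy	imaging reveals depression fracture of the skull.
decoy	no respiratory depression observed on monitoring.
decoy	monitor for respiratory depression while on opioids.
decoy	repeat ekg without st depression or elevation.
filler	patient is doing well postoperatively.
filler	vital signs stable and patient afebrile overnight.
filler	incision clean, dry, and intact.
filler	ambulating in hallway without assistance.
filler	diet advanced as tolerated this morning.
filler	plan to continue current management.
filler	follow up in clinic in two weeks.
filler	pain controlled with current regimen.
filler	patient in no acute distress on exam.
filler	labs reviewed and within normal limits.
filler	patient lives at home with family support.
filler	medication list reviewed and reconciled.
filler	surgical wound healing appropriately.
filler	physical therapy evaluation completed at bedside.
filler	breath sounds clear bilaterally on auscultation.
filler	abdomen soft and nontender on palpation.
filler	discharge planning discussed with care team.
filler	patient voiding spontaneously without difficulty.
ssri_affirmed	continue sertraline 50 mg daily.
ssri_affirmed	patient takes fluoxetine for mood disorder.
ssri_affirmed	started on citalopram 20 mg by psychiatry.
ssri_affirmed	home medications include escitalopram 10 mg.
ssri_affirmed	refill provided for paroxetine today.
ssri_negated	discontinued prozac years ago, denies current use.
ssri_negated	patient stopped sertraline last month on her own.
ssri_negated	no longer taking citalopram per patient report.
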