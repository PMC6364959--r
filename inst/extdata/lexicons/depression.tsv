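term	kind
depression	concept
depressed	concept
depressive	concept
major depressive disorder	concept
major depression	concept
depressive disorder	concept
mdd	concept
dysthymia	concept
dysthymic disorder	concept
anhedonia	concept
hopelessness	concept
low mood	concept
depressed mood	concept
depressive symptoms	concept
persistent sadness	concept
feeling down	concept
feels down	concept
st depression	exclusion
st segment depression	exclusion
st elevation or depression	exclusion
ecg depression	exclusion
ekg depression	exclusion
depression fracture	exclusion
depressed skull fracture	exclusion
depressed fracture	exclusion
skull depression	exclusion
respiratory depression	exclusion
bone marrow depression	exclusion
cns depression	exclusion
myocardial depression	exclusion
tibial plateau depression	exclusion
no	pre_neg
not	pre_neg
without	pre_neg
denies	pre_neg
denied	pre_neg
deny	pre_neg
negative for	pre_neg
no evidence of	pre_neg
no history of	pre_neg
no signs of	pre_neg
no symptoms of	pre_neg
no complaints of	pre_neg
free of	pre_neg
absence of	pre_neg
never had	pre_neg
rules out	pre_neg
ruled out	pre_neg
does not have	pre_neg
doesn't have	pre_neg
resolved	pre_neg
unlikely	post_neg
ruled out	post_neg
was ruled out	post_neg
is ruled out	post_neg
has resolved	post_neg
is not present	post_neg
not present	post_neg
was negative	post_neg
is negative	post_neg
but	termination
however	termination
although	termination
though	termination
except	termination
aside from	termination
apart from	termination
nevertheless	termination
other than	termination
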