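term	kind
sertraline	concept
zoloft	concept
fluoxetine	concept
prozac	concept
sarafem	concept
citalopram	concept
celexa	concept
escitalopram	concept
lexapro	concept
paroxetine	concept
paxil	concept
pexeva	concept
fluvoxamine	concept
luvox	concept
vilazodone	concept
viibryd	concept
no	pre_neg
not	pre_neg
denies	pre_neg
denied	pre_neg
without	pre_neg
discontinued	pre_neg
stopped	pre_neg
stop	pre_neg
off	pre_neg
no longer taking	pre_neg
no longer on	pre_neg
never took	pre_neg
never taken	pre_neg
allergic to	pre_neg
declined	pre_neg
was discontinued	post_neg
was stopped	post_neg
discontinued	post_neg
stopped	post_neg
but	termination
however	termination
although	termination
though	termination
except	termination
and restarted	termination
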