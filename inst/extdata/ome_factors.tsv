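ingredient	route	factor
morphine	oral	1
morphine	iv	3
oxycodone	oral	1.5
hydrocodone	oral	1
codeine	oral	0.15
tramadol	oral	0.1
hydromorphone	oral	4
hydromorphone	iv	20
fentanyl	iv	100
fentanyl	transdermal	2.4
methadone	oral	3
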