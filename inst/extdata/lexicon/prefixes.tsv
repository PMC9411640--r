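form	kind	combining_forms	meanings	organ_system
dys	prefix	dys	painful
choledoch	prefix	choledocho	common,bile,duct	digestive
peri	prefix	peri	surrounding
hyper	prefix	hyper	excessive
hypo	prefix	hypo	deficient,or,below
brady	prefix	brady	slow
tachy	prefix	tachy	fast
endo	prefix	endo	within
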