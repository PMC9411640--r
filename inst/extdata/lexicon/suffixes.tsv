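form	kind	combining_forms	meanings	organ_system
pnea	suffix	pnea	breathing	respiratory
itis	suffix	itis	inflammation
dynia	suffix	dynia	pain,discomfort
ism	suffix	ism	state,of,or,condition
rrhea	suffix	rrhea	flow,excessive,discharge
sclerosis	suffix	sclerosis	hardening
spasm	suffix	spasm	sudden,or,involuntary
lithiasis	suffix	lithiasis	calculus,or,stone
emia	suffix	emia	blood,condition
algia	suffix	algia	pain
ectomy	suffix	ectomy	surgical,removal
megaly	suffix	megaly	enlargement
osis	suffix	osis	abnormal,condition
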