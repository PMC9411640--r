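rule_id	singular_suffix	plural_suffix
r_ix	ix	ices
r_nx	nx	nges
r_ma	ma	mata
r_is	is	es
r_um	um	a
r_us	us	i
r_a	a	ae
r_y	y	ies
r_x	x	ges
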