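name	delta_mono	delta_avg	site_rule	per_site
disulfide_bond	-2.015650	-2.01588	C	TRUE
carbamidomethyl	57.021464	57.0513	C	TRUE
ring_open_hydration	18.010565	18.01528	cyclic	FALSE
amidation	-0.984016	-0.98476	cterm	FALSE
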