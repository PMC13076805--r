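>psysol3 topology=cyclic disulfides=5-19,9-21,14-27
GLPTCFETCILGTCYTPGCSCSTYRLCLNN
>oxytocin disulfides=1-6 mods=amidation
CYIQNCPLG
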