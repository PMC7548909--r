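>IKBKB_synthetic_amplicon mutation=duplication position=35 ref=G
AGGAATCTCGCCTTCTTCCGCGGGCCGGCCGCCCGCCGGGCGGCGGGCCCGTCTGGCACA
GCATCCAG
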