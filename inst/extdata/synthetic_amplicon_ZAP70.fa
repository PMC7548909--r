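>ZAP70_synthetic_amplicon mutation=substitution position=42 ref=G alt=A
TGAGGAGGAGGACACTGGCTTCTGGGCGATCAGCAAGTCACGCTCAAAGGGAGATCATAT
AGGAAACTTCATCGAGCAGGGCAA
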