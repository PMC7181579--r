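fam1 ind1 0 0 1 1 A A G G
fam2 ind2 0 0 1 2 A C G T
fam3 ind3 0 0 1 2 C C G T
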