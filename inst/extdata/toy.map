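6 rs001 0 32400000
6 rs002 0 32500000
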