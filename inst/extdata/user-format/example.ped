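F1 I1 0 0 1 2 A A A C G G T T
F2 I2 0 0 2 1 A C C C G T T T
F3 I3 0 0 1 2 A A C C G G A T
F4 I4 0 0 2 1 C C A C T T A A
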