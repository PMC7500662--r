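1 rs1 0 1000
1 rs2 0 2000
1 rs3 0 3000
1 rs4 0 4000
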