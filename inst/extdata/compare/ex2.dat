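0 SNP1 0 0

0 SNP2 0 0
0 SNP3 0 0
0 SNP4 0 0
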