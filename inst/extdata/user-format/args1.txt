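# two output files: a space-delimited genotype matrix (.geo) with fused
# cells and an "ID SNP1..SNPm" header, plus a tab-delimited marker list
# (.snp) carrying the RS identifiers
MATRIX
file, 1
orientation, samples-as-rows
cell, fused
delimiter, space
delimiter, tab, 2
VECTOR
IndividualID, 1
SNPID, 1, 2
INSERT
row, 1, ID, SNP$
2, row, 1, SNP
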