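# single space-delimited output: id, sex and phenotype columns, split
# allele cells, header row with allele-column serials
MATRIX
file, 1
orientation, samples-as-rows
cell, split
delimiter, space
VECTOR
IndividualID, 1
Sex, 2
Phenotype, 3
INSERT
row, 1, ID, Sex, Pheno, A#
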