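# pedkit

Genome-wide association studies (GWAS) revolve around PLINK, but the wider
tool ecosystem — epistasis scanners, multifactor dimensionality reduction,
logic regression, resequencing browsers — each expects its own genotype
file layout. pedkit is an R toolkit for moving case/control genotype data
between those worlds without loss: bit-exact PLINK PED/MAP, BED/BIM/FAM and
TPED/TFAM codecs, exporters/importers for the common third-party dialects,
a small text DSL for layouts nobody anticipated, and the file utilities
(reference-keyed comparison, transposition, row/column editing, sample-wise
splicing) that format surgery always ends up needing. It is written for
analysts who assemble GWAS pipelines and for tool authors who need
reproducible fixtures: a built-in simulator generates datasets under
Hardy–Weinberg proportions so everything can be exercised offline.

## What it computes

The core container is a `ped_dataset`: samples × markers with the six
pedigree columns and unordered allele-pair calls (`"AC" ≡ "CA"`, `"00"` =
missing). On top of it:

* **Allele summaries** — per SNP, the major/minor allele by count (ties
  broken deterministically by ASCII order), with the conservation identity
  `major_count + minor_count + 2·missing = 2n`.
* **Normalization** — rewrite each column over the `D`/`d`/`N`
  (major/minor/missing) alphabet; idempotent, and the basis for lifting
  numeric codings back to genotypes.
* **Tied-allele swap** — exchange the two allele characters of SNPs whose
  alleles occur equally often (`AA AC CC → CC CA AA`); an involution.
* **QC during conversion** — the 1-df Pearson chi-square test of
  Hardy–Weinberg equilibrium, X² = Σ (O − E)²/E with E = (np², 2npq, nq²),
  plus per-sample and per-SNP missing-rate filters, applied in a fixed
  order (SNP missingness → sample missingness → HWE) with a removal log.
* **Codings** — additive (minor-allele count 0/1/2) and letter-order
  (alphabetical genotype classes) for the numeric export formats.
* **2-bit BED** — SNP-major v1.00: four genotypes per byte, low bits
  first, `00` hom-A1, `01` missing, `10` het, `11` hom-A2; one sixteenth
  of the equivalent PED text.

## A worked example

```r
library(pedkit)

ds <- sim_ped_dataset(8, 5, missing_rate = 0.1, seed = 1)
allele_summary(ds)
#> # A tibble: 5 × 9
#>   snp_id major minor major_count minor_count missing_calls is_tied
#>   <chr>  <chr> <chr>       <int>       <int>         <int> <lgl>
#> 1 rs1    A     G               8           8             0 TRUE
#> 2 rs2    A     G              10           6             0 FALSE
#> 3 rs3    C     0              12           0             2 FALSE
#> 4 rs4    C     G              10           6             0 FALSE
#> 5 rs5    G     T              10           4             1 FALSE
```

`rs1` is *tied* (8 of each allele): `swap_tied_alleles()` would relabel it
and nothing else; `rs3` is monomorphic (minor `"0"`), and its two missing
calls explain `missing_calls = 2`. Round-trip it through the binary codec
and a third-party format:

```r
write_bed(ds, "x.bed", "x.bim", "x.fam")
back <- read_bed("x.bed", "x.bim", "x.fam")     # identical unordered calls

export_dataset(ds, "mdr", "x.mdr")              # tab-delimited, Class last
import_dataset("x.mdr", "mdr")                  # genotypes return as D/d
```

Comparing two files on a reference column instead of line-by-line:

```r
ex <- system.file("extdata/compare", package = "pedkit")
compare_files(file.path(ex, "ex1.dat"), file.path(ex, "ex2.dat"))
#> <file_comparison> mode=sequential
#>   differing rows: 5
compare_files(file.path(ex, "ex1.dat"), file.path(ex, "ex2.dat"),
              mode = "reference", ref_col = 2)
#> <file_comparison> mode=reference (reference column 2)
#>   differing rows: 1
```

The same two files differ in five rows when read line-by-line, but keyed
on their marker-name column they differ in a single row — in column 4.

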