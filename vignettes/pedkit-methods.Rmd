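---
title: "Genotype file conversion, comparison and QC with pedkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genotype file conversion, comparison and QC with pedkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pedkit)
```

pedkit moves case/control genotype data between PLINK's pedigree formats
and the file layouts of other GWAS analysis tools, with optional quality
control applied on the way through. This vignette is the package's account
of the models and conventions behind that: what is computed, which choices
were genuinely open and how they were fixed, and what the shipped tests do
and do not demonstrate.

## The dataset model

A `ped_dataset` holds three aligned pieces: an ordered sample table (the
six pedigree columns: family, individual, father, mother, sex, phenotype),
an ordered marker table (chromosome, marker id, genetic distance, physical
position), and an n × m grid of genotype calls. A call is an *unordered*
pair of single-character alleles: `"AC"` and `"CA"` are the same genotype
everywhere in the package, and `"00"` is a missing call. Multi-character
allele tokens are reduced to their first character on read (with a
warning), and a half-missing call such as `"A0"` carries no usable
information for a biallelic marker, so it is normalized to fully missing,
again with a warning — the same convention PLINK applies.

Marker order is load-bearing. Every conversion preserves it, because
downstream tooling (and manual inspection) often relies on positional
correspondence between files; the TPED pathway exists largely so that
transposed data can reach PED/BED without any reordering.

### Major and minor alleles

`allele_summary()` tallies every non-missing allele occurrence per column.
The more frequent allele is the major one; when the two counts are equal
the column is *tied* and the allele with the lower ASCII code is declared
major. Any deterministic rule would do — the data cannot distinguish the
two labellings — but a fixed rule is what makes round trips and golden
files byte-reproducible, and ASCII order needs no extra state. The same
rule resolves ties everywhere (BIM allele columns, numeric codings,
normalization), and it is applied with explicit code-point comparisons so
results do not depend on the session locale. Columns with one allele
report minor `"0"`; columns with more than two distinct alleles are an
error that names the marker, since everything downstream assumes
biallelic markers.

Two derived operations build on the summary. *Normalization* rewrites
each column over a three-letter alphabet — `D` for the major allele, `d`
for the minor, `N` for missing — so the composition of a column is
readable at a glance; heterozygotes are written in the canonical order
`Dd`. Because `D` (code 68) sorts before `d` (code 100), the tie-break
keeps `D` major on a second pass and the operation is idempotent; for the
same reason `N` must count as missing during allele tallying, which the
package does (both `0` and `N` are missing characters). *Swapping*
exchanges the two allele characters in exactly the tied columns. The
marker's information content is unchanged, but files produced by
different tools can disagree on tied columns' labels, and swapping makes
such files comparable; applying it twice restores the input.

## Quality control

`hwe_chi2()` is the one-degree-of-freedom Pearson chi-square test of
genotype counts against Hardy–Weinberg proportions at the sample allele
frequency p̂: expected counts (np̂², 2np̂q̂, nq̂²), statistic
Σ (observed − expected)² / expected. A monomorphic marker has nothing to
test, and is reported as statistic 0, p = 1 by documented convention. An
exact test would behave better at very low minor-allele counts, but the
chi-square form is the verifiable default and matches how most pipelines
report HWE; an exact variant is deliberately out of scope.

`apply_qc()` runs up to three filters, each disabled unless its threshold
is set, in a fixed order: markers failing the per-SNP missing-rate bound,
then samples failing the per-sample bound, then markers failing the HWE
p-value floor — with rates and genotype counts recomputed between steps,
since removing samples changes per-marker quantities. The order itself is
a free choice; fixing and documenting one (most-damaged markers first, so
they cannot knock out otherwise-fine samples) is what makes results
reproducible. Every removal is logged with the measured value and the
threshold it violated.

## The binary codec

BED files are written and read only in the SNP-major v1.00 variant (magic
`0x6C 0x1B`, mode byte `0x01`): per marker, `ceiling(n/4)` bytes, four
genotypes per byte packed low-bits-first, with `00` = homozygous
allele-1, `01` = missing, `10` = heterozygous, `11` = homozygous
allele-2. Allele-1 is the minor allele and allele-2 the major, recorded in
BIM columns 5–6; padding bits are zero. Individual-major files (mode
`0x00`) are rejected with a clear message rather than silently
misdecoded — modern PLINK has defaulted to SNP-major for a long time.
Because a byte stores what text stores in sixteen (four genotypes of
"A C " each), a BED payload is almost exactly one sixteenth of its PED
equivalent; the acceptance suite verifies the ratio at 1,000 × 10,000.
One free choice: a heterozygote decoded from BED is written to text as
"minor major". Any order is valid under unordered-call semantics; fixing
one makes text output byte-reproducible.

The `.tsnp` sidecar of transposed filesets carries RS identifiers, one row
per TPED row, and replaces the TPED's own marker ids on read. Its exact
column layout is not standardized, so the RS-bearing column index is a
parameter (default: first column).

## Third-party formats

Each supported dialect is a registry entry — orientation, coding,
delimiter, missing code, header and phenotype placement — and the
registry is the single dispatch point for `export_dataset()` /
`import_dataset()`. Two genotype codings are shared: *additive* (count of
minor alleles, 0/1/2, missing 3 or the format's own code) and
*letter-order* (genotype classes numbered alphabetically, regardless of
which allele is major). Layout details per dialect are frozen as golden
expectations in the test suite; correcting a dialect later means editing
one descriptor.

Numeric codes destroy the original allele letters, so importing a coded
format lifts codes onto the `D`/`d` alphabet — exactly the image of
`normalize_genotypes()`, which is the round-trip identity the tests
assert. For letter-order input the major class is recovered from the
imported counts themselves (the coding is invertible up to labels).
Raw-allele formats (PrettyBase, GEO matrices, linkage rows) restore the
original letters. PrettyBase files come in a tab-delimited four-field
dialect and a space-delimited variant; the dialect is auto-detected from
the first data line's delimiter signature and logged. Formats that carry
no phenotype column (PrettyBase, GEO) cannot return one — an
information-theoretic limit, not an implementation gap — so the round-trip
property is asserted for phenotypes only where a format encodes them.
Logic-regression export recodes the additive value under a genetic model
(dominant: g ≥ 1; recessive: g = 2; additive: g) with the phenotype
written as-is or mapped to 0/1 ("logited"), six combinations in all;
dominant and recessive recodings are many-to-one, so this format is
export-only.

## User-defined layouts

Layouts nobody anticipated are described by an *arguments file*: a
line-oriented, comma-delimited text with three case-insensitive sections.
MATRIX fixes the genotype block (which output file, samples-as-rows or
snps-as-rows, fused `"AC"` cells or split `A C` fields, per-file
delimiter); VECTOR maps pedigree/marker fields to absolute 1-based
row/column positions of the emitted file (a per-sample field runs along
the sample axis, so `Sex, 2` is column 2 when samples are rows); INSERT
places generated rows/columns built from wildcard patterns: `#`, `$` and
`@` expand to allele, marker and sample serial numbers, `^ab` alternates
two characters with period 2, and backslash escapes (`\#`, `\$`, `\@`,
`\^`, `\,`, `\t`) yield literals. Trailing empty items are ignored.
Positions count all rows/columns of the final file — the same convention
the comparison report uses — and collisions are rejected before anything
is written. When the arguments file named in a conversion does not exist,
a commented template is generated instead and the conversion aborts; the
template itself parses cleanly and is byte-stable.

The grammar is this package's own freezing of the section/wildcard design:
only the section roles and the wildcard table have an external
specification, so the concrete key names and position semantics here are
documented by the shipped example (`inst/extdata/user-format/`) and the
round-trip property: `user_to_ped(ped_to_user(ds, spec), spec)` restores
the genotype grid and every mapped field, over random datasets, both
orientations, both cell layouts and multi-file outputs.

## File utilities

*Comparison* normalizes whitespace (runs of spaces/tabs collapse, ends
trimmed) and then either pairs rows by position — where an empty or
surplus row counts as one differing row with every affected column
flagged — or pairs them by the value of a reference column, in which case
order is irrelevant, keys present on one side only are reported separately
rather than as differences, and duplicate keys are an error. The shipped
example pair differs in five rows sequentially but in exactly one row
(column 4) under its key column: reordering plus one stray empty row
accounts for everything else. Files containing NUL bytes are compared
bytewise.

*Transposition* has two modes with byte-identical output: speed-first
materializes the grid; memory-first makes one pass per block of columns
(512 by default) and never holds more than a block, at the cost of
re-reading the input. Auto mode estimates the in-memory requirement as
file size × 2 × 1.2 — characters to fields plus bookkeeping, with a
safety factor — and falls back to memory-first above a configurable
budget (default 1 GiB), logging the decision.

*Splicing* merges the **samples** of two PED filesets (PLINK's own merge
combines markers). The first file dominates: output markers follow A's
order with B-only markers appended in B's order; genotypes missing from
one side are `"00"`; B samples whose full six-column pedigree prefix
equals an A sample's are dropped — the six-tuple, never a subset, defines
sample identity, and A's copy wins. A marker that becomes multi-allelic
across the two sources aborts the splice naming the marker. Exactly two
files per call; repeat to splice more.

## The simulator

`sim_ped_dataset()` draws, per marker, a minor-allele frequency uniformly
from `maf_range` (default 0.05–0.5, the polymorphic range a GWAS panel
targets), two distinct allele letters, and then genotype classes from the
Hardy–Weinberg probabilities (p², 2pq, q²) — classes directly, not two
independent allele draws per individual, so the chi-square QC test is
exactly calibrated against the generator: over 1,000 simulated markers at
n = 1,000 the fraction with p < 0.05 sits at 0.05 ± 0.02, and the
acceptance suite checks precisely that. Missing calls are masked in
afterwards at `missing_rate`; phenotypes are case (`2`) for the first
⌈`case_fraction`·n⌉ samples. A seed fixes everything, and identical
configurations produce byte-identical files.

What the simulator does *not* emulate — linkage disequilibrium,
population structure, relatedness, genotyping-batch artefacts — is
exactly what format conversion never looks at, so passing tests certify
the codecs and utilities, not any statistical behaviour on structured
real data. The QC filters are likewise tested for their filtering
semantics, not for scientific effectiveness on real cohorts.

## Problem sizes and numerical choices

The test and acceptance runs use 100 random fixtures (≤ 12 × 8) for the
PLINK round trip, 50 random layout specs, 1,000 oracle triples for the
HWE statistic (agreement to 1e-9), a 1,000 × 1,000 calibration panel and
a single 1,000 × 10,000 dataset for the size-ratio check — sizes chosen
so the whole suite exercises every path in well under ten minutes on one
core while keeping the statistical checks several standard deviations
wide of their bounds. Counts are integers throughout; the only floating
point arithmetic is the chi-square statistic and the rate computations,
none of which accumulate across more than three terms.

## Known limitations

PLINK 2 PGEN, VCF, dosage and BGEN formats are out of scope, as is
writing individual-major BED. The HWE test is the chi-square
approximation only, and is not X-chromosome aware. Comparison is textual
or bytewise by design — it does not know that `"AC"` equals `"CA"`; use
normalization (and swapping for tied markers) to canonicalize files
before a genotype-aware diff. The arguments-file DSL covers rectangular
layouts with per-axis vectors and inserted rows/columns; nested or
conditional structure is not expressible.
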