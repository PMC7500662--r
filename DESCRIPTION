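Package: pedkit
Title: Conversion, Comparison and Quality Control for PLINK Pedigree
    Genotype Files
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Lossless, order-preserving conversion between PLINK PED/MAP,
    binary BED/BIM/FAM and transposed TPED/TFAM genotype filesets and the
    input formats of common genome-wide association analysis tools (BEAM,
    BOOST, MDR, SVMSNPs, logic regression, PrettyBase, GEO-style matrices,
    linkage), plus a small text DSL for user-defined layouts, file
    utilities (sequential and reference-keyed comparison, dual-mode
    transposition, row/column insertion and deletion, sample-wise splicing
    of pedigree files) and optional per-marker and per-sample quality
    control (Hardy-Weinberg equilibrium, missing-call rates) applied
    during conversion.  A synthetic genotype simulator generates
    reproducible test data under Hardy-Weinberg proportions.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    rlang,
    stats,
    tibble,
    utils,
    withr
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
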