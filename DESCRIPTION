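Package: xq22cgr
Title: Modeling Complex Genomic Rearrangements at an Inverted-Repeat Locus
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Constructive models of complex genomic rearrangements (CGRs) at
    an inverted-repeat-flanked locus, built around the PLP1/Xq22.2 low-copy
    repeat array: NAHR-mediated inversion alleles, DUP-TRP/INV-DUP products,
    nested deletions, and rolling-circle quadruplications, each represented as
    an ordered list of oriented reference segments stitched by breakpoint
    junctions. From a modeled allele the package derives copy-number profiles,
    junction multisets, and in-silico predictions of orthogonal assays
    (Southern restriction-fragment dosage, qPCR/dPCR copy counts, marker
    zygosity, fosmid end-pair inversion genotyping). A junction caller
    characterizes template switches from sequence (microhomology, blunt joins,
    templated insertions, de novo mutations), a PSV toolkit localizes
    crossovers within near-identical repeat paralogs, and a seeded simulator
    generates synthetic loci, rearranged genomes, fosmid libraries, junction
    reads and aCGH-style probe tables for fully offline testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
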