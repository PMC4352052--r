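# xq22cgr

Constructive models of complex genomic rearrangements (CGRs) at an
inverted-repeat-flanked locus, built around the *PLP1*/Xq22.2 low-copy
repeat (LCR) array on the human X chromosome (hg19 coordinates).

## What it is for

The Xq22.2 repeat array distal to *PLP1* — outer C/D repeats (~40 kb, 93%
identity), middle A1a/A1b repeats (~20 kb, 99% identity), inner A2/A3
repeats — mediates both a common copy-neutral inversion polymorphism
(haplotypes H1/H2, via non-allelic homologous recombination between
A1a/A1b) and pathogenic copy-number gains: DUP-TRP/INV-DUP products,
duplications with nested deletions, and a rolling-circle quadruplication.
Because the repeats are nearly identical, breakpoints inside them cannot be
sequenced directly, and the evidence for each product structure is a
combination of orthogonal assays.

This package is for researchers modeling such rearrangements. It represents
every allele as an ordered list of oriented reference segments stitched by
breakpoint junctions, and *derives* all observables from that one
representation:

* **Copy-number profiles** (`copy_number_profile()`), with the reporting
  convention that snaps in-repeat transitions to the canonical endpoint
  anchors (triplication endpoint ChrX:103223671, duplication endpoint
  ChrX:103324335), reproducing published size arithmetic such as
  103223671 − 103145195 = 78476.
* **Assay predictions**: Southern restriction-fragment dosage
  (`southern_profile()`, 25 kb H1 / 29 kb H2 probe fragments; 2:1 dosage for
  products formed on H2), qPCR primer-pair copy counts
  (`qpcr_copy_number()`), digital-PCR junction copies per genome
  (`dpcr_copies_per_genome()`, `junction_multiplicity()`), marker zygosity
  for intra- vs inter-chromosomal origin (`marker_zygosity()`), and
  PSV-specific PCR amplicon classes (`predict_psv_pcr()`).
* **Sequence-level callers**: junction signature decomposition
  (`call_junction()` — microhomology / blunt / templated insertion, with
  de novo mutation flagging), insertion template search
  (`locate_insertion_template()`), and crossover localization between
  repeat paralogs via paralogous sequence variants (`call_psvs()`,
  `map_crossover()`).
* **Inversion genotyping**: discordant fosmid end-pair support
  (`call_inversion_support()`), Southern band quantitation
  (`quantitate_genotype()`), sex-aware allele frequencies
  (`allele_frequencies()`), and phasing of structural genotypes onto SNP
  haplotypes (`phase_sv_on_snps()`).
* **A seeded simulator** (`sim_config()`, `make_locus_sequence()`,
  `simulate_rearranged_genome()`, `simulate_fosmid_pairs()`,
  `simulate_junction_reads()`, `simulate_acgh()`) generating synthetic
  inputs with planted truth, so the whole pipeline is testable offline.
* **Structure reconciliation** (`reconcile_structure()`,
  `recover_event_type()`): a finite grammar matcher that re-identifies each
  product type from its profile and junction multiset.

All user-facing functions take data frames first and return tibbles, so
calls chain with the pipe; allele and locus objects are light S3 classes
with `tidy()`/`glance()` methods and `autoplot()` for profiles and band
patterns.

## Worked example

Model the largest published DUP-TRP/INV-DUP (P250-style endpoints) as
having arisen on the inverted H2 haplotype of a male genome, then predict
its assays:

```r
library(xq22cgr)

locus <- plp1_locus()
al <- build_dup_trp_inv_dup(locus,
  trp_start = from_printed(103145195),
  dup_start  = from_printed(102866025),
  progenitor = "H2")

size_arithmetic(al)
#> # A tibble: 1 x 4
#>   trp_start trp_size dup_start dup_size
#> 1 103145195    78476 102866025   458310

southern_profile(al)
#> # A tibble: 2 x 2
#>    size count
#> 1 25000     1
#> 2 29000     2

classify_progenitor(band_dosage_ratio(southern_profile(al)))
#> [1] "H2_origin"

qpcr_copy_number(al)
#> # A tibble: 3 x 3
#>   pair      copies ratio_to_control
#> 1 black          4              2
#> 2 red            3              1.5
#> 3 red_black      3              1.5

recover_event_type(al)
#> [1] "dup_trp_inv_dup"
```

The triplication/duplication sizes are exactly the published endpoint
differences; the Southern prediction shows three probe copies at 2:1
29 kb : 25 kb dosage (two copies of the progenitor H2 context, one
"flipped" to H1), from which the classifier recovers the progenitor; the
qPCR pairs show 4 copies of the repeat-internal target and 3 of the
triplicated unique target (vs 2 and 1 in a reference male); and the
grammar matcher re-identifies the product from its own derived profile and
junctions.

Inversion-polymorphism genotyping works from the shipped fixtures:

```r
allele_frequencies(read_genotype_fixture())
#> # A tibble: 1 x 5
#>   n_haplotypes count_H1 count_H2 freq_H1 freq_H2
#> 1           31       18       13   0.581   0.419
```

## Shipped data

Small plain-text fixtures under `inst/extdata/`: the 16-row junction table
(endpoints and junction descriptors), the locus architecture as BED + JSON
config (round-trips with `plp1_locus()`), and synthetic fosmid-support,
genotype-count and SNP-phasing tables whose construction is described in
`?read_fosmid_fixture`. Files suffixed `_synthetic` are built from
published summary descriptions, not from deposited data.

See the methods vignette (`vignettes/cgr-modeling.Rmd`) for the model
conventions, assay geometry, simulator assumptions and known limitations.
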