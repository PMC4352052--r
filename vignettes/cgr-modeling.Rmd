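---
title: "Modeling complex genomic rearrangements at an inverted-repeat locus"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling complex genomic rearrangements at an inverted-repeat locus}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(xq22cgr)
```

## The problem

The Xq22.2 region distal to *PLP1* carries a nested array of inverted
low-copy repeats (LCRs): outer C/D repeats (~40 kb, ~93% identity), middle
A1a/A1b repeats (~20 kb, ~99% identity), and inner A2/A3 repeats (~10 kb,
~87% identity). This architecture supports two very different kinds of
structural variation:

* a **benign, copy-neutral inversion polymorphism** between A1a and A1b
  (reference haplotype H1, inverted haplotype H2), created by non-allelic
  homologous recombination (NAHR) between the near-identical paralogs; and
* **pathogenic copy-number gains** — DUP-TRP/INV-DUP products, nested
  deletions inside duplications, and a rolling-circle quadruplication —
  whose distal breakpoints are funneled into the same repeats.

Because the repeats are nearly identical, neither arrays nor short reads can
place breakpoints inside them, and the wet-lab evidence in this field is a
mosaic of orthogonal assays: aCGH copy-number profiles, breakpoint junction
sequencing, Southern blot band dosage, semi-quantitative and digital PCR,
marker genotyping, and fosmid end-pair orientation. This package implements
the computational core of that reasoning: constructive allele models from
which every assay readout is *derived*, plus the sequence-level callers
(junction signatures, paralogous sequence variant crossovers) used to read
evidence back out of data.

## The allele model

An allele (`cgr_allele`) is an ordered list of oriented reference segments
plus the junction list that stitches them. It is the single source of truth:
copy-number profiles (`copy_number_profile()`), junction multisets
(`junction_multiset()`), product sequences (`emit_sequence()`) and assay
predictions (`southern_profile()`, `qpcr_copy_number()`,
`predict_psv_pcr()`) are all derived from it, never stated independently.
This is what makes the round trips in the test suite meaningful: a
brute-force per-base coverage count over the segment list must equal the
analytic profile, and the structure grammar must re-identify every
constructed event from its own derived observables.

Event constructors:

* `apply_inversion()` — NAHR between a repeat pair at a crossover offset
  within the aligned repeat frame. The spacer is reverse-complemented and
  both repeats become reciprocal chimeras. Applying the same inversion twice
  restores the input exactly (an involution, tested at sequence level).
* `build_dup_trp_inv_dup()` — the duplication–inverted
  triplication–duplication product: a direct copy into the distal repeat up
  to the Jct1 template switch, an inverted copy back to the proximal
  triplication endpoint, then Jct2 into a direct copy. Four copy-number
  transitions, two junctions.
* `apply_nested_deletion()` — removes an interval from one duplicated copy,
  producing the copy-number-neutral segments seen inside some duplications.
* `build_rolling_circle_quadruplication()` — a template switch at the
  distal circle boundary re-invades the proximal boundary (establishing
  junction), replication traverses the circularized segment repeatedly, and
  a terminating switch exits proximally. With a roll of just under two full
  circles, the establishing junction is present twice and the terminator
  once — exactly the junction copy numbers that digital PCR measures.

Events compose: a product built with `progenitor = "H2"` is constructed on
the inversion allele's product chromosome, so its Jct1 sits between the
*chimeric* repeats of H2. That provenance changes which Southern fragments
flank each probe copy (the basis of progenitor-haplotype classification)
while leaving the copy-number profile unchanged — both facts are tested.

## Coordinates and the anchor-snapping convention

Internally every interval is 0-based half-open; all printed output is
1-based inclusive, so published endpoint arithmetic is reproduced exactly
(e.g. 103223671 − 103145195 = 78476 bp of triplication for the largest
P250-style allele). Two conventions deserve emphasis:

* **Canonical distal anchors.** All DUP-TRP/INV-DUP products share the
  approximate triplication endpoint ChrX:103223671 and duplication endpoint
  ChrX:103324335 (hg19). In the fixture these are the proximal edges of A1a
  and A1b — consistent with the published phasing interval that runs
  "from A1a to A1b" between exactly those coordinates. A consequence worth
  recording: with those anchors the A1a–A1b spacer is ~80 kb, although the
  same source also describes the repeats as "separated by ~50 kb"; the
  fixture follows the coordinates, since the size arithmetic depends on
  them.
* **Anchor snapping.** True per-base coverage of a DUP-TRP/INV-DUP places
  the 3→2 and 2→1 transitions *inside* A1a and A1b, at the Jct1 crossover
  offset. Hybridization arrays cannot resolve positions within 99%-identical
  paralogs, and published endpoint tables report the repeat edges instead.
  `copy_number_profile(snap = TRUE)` therefore moves in-repeat transitions
  of the mediating pair to the canonical anchor edges; `snap = FALSE` (the
  default) returns raw coverage and is what the brute-force oracle checks.

## Assay geometry

The BssSI site coordinates at the real locus are not published; what is
published is the assay's output (25 kb reference fragment, 29 kb inverted
fragment, dosage 2:1 in affected males). The fixture therefore *engineers*
the site positions — symmetric around A1a/A1b at offsets −4 kb, +21 kb
(spacer, proximal side) and −25 kb, +4 kb (spacer, distal side) — so that
the probe fragment is exactly 25 kb on H1 and 29 kb on H2 at scale 1. This
is flagged `engineered_to_band_sizes` in the shipped config. The important
property is that the patient dosages are *not* engineered: 2:1 and 1:2
ratios for H2- and H1-progenitor products, and the 25 kb band of the
"flipped" copy inside an H2 product, emerge from walking the digest through
the product segment list, independent of the Jct1 crossover offset (the
offsets cancel; the suite checks this across a parameter grid).

qPCR primer targets follow the published scheme: a "black" pair internal to
both A1a and A1b (2 copies in a reference male), a "red" pair in unique
sequence proximal to A1a (1 copy), and a "red/black" pair straddling the
A1a proximal edge. A primer pair amplifies once per contiguous occurrence of
its target in the product, in either orientation; the modeled
DUP-TRP/INV-DUP yields 4 black and 3 red copies, a plain tandem duplication
4 and 2. Digital PCR normalization is the published formula
`copies/genome = jct / (RNaseP / 2)` with RNase P autosomal.

## Sequence-level callers

`call_junction()` decomposes a junction-spanning read against its two
templates: maximal anchored prefix and suffix matches, with
`overlap > 0` reported as microhomology (always an exact overlap — isolated
mismatches can extend a flank match, are reported as candidate de novo
mutations, and never extend microhomology), `overlap == 0` as a blunt join,
and `overlap < 0` as an insertion, optionally resolved against a template
search space into further switches (with a U-turn annotation when the
templates lie on opposite strands within 1 kb). The junction point is
reported as the microhomology span, never a single base, because the data
cannot distinguish positions within the overlap. The caller is validated
against an exhaustive split-point oracle on thousands of random planted
junctions, and for reverse-complement symmetry.

`call_psvs()` and `map_crossover()` implement crossover localization inside
the repeats: PSVs are the substitution columns between paralogs (column-wise
for equal-length paralogs, which is exact for the generator's
substitution-only divergence model; global affine-gap alignment — match 1,
mismatch −2, gap open −5, extend −1 — otherwise, with indel columns kept as
length-variant tracts rather than PSVs). The crossover call is the maximal
interval between the last PSV matching one paralog and the first matching
the other, with the boundary chosen to minimize inconsistent PSVs; isolated
inconsistencies are reported as gene-conversion-like secondaries, two or
more consecutive ones force a multi-switch report, and intervals wider than
8 kb are labeled unresolvable — reproducing the behavior of real chimeric
clones whose switch falls in a PSV desert.

## The synthetic-data generator

`make_locus_sequence()` draws i.i.d. uniform background sequence and builds
each right paralog by copying the left one with per-base substitutions at
rate 1 − identity (reverse-complemented for inverted pairs). That is the
simplest model consistent with the stated identities; it deliberately omits
indel divergence within repeats, repeat-internal homopolymers, GC structure
and sequencing error, so passing tests demonstrate correctness of the
calling logic, not robustness to real-data noise. Fosmid libraries use
uniform clone starts, uniform 32–48 kb inserts (scaled), and end
orientations derived by mapping ends through the product segment map —
discordance is therefore deterministic given the structure, which is why
the false-call rate on reference genomes is exactly zero. Junction reads are
600 bp (the sequencing convention for these junctions), with de novo
mutations planted at 2 per 15 kb. aCGH tables are `log2(state)` plus
Gaussian noise; the shipped segmenter is a deliberately simple
sliding-window mean-shift detector (window 5 probes, threshold 0.4 log2
units), not a reimplementation of any vendor pipeline.

Every generator takes its randomness from `sim_config(seed)`; identical
configs give byte-identical outputs.

## Problem sizes and defaults

The default working scale for simulations is 1/10 (a 450 kb locus), at
which a full build–profile–reconcile cycle is milliseconds and the whole
suite runs in about a minute; sequence-level round trips use scale 1/50.
Fosmid geometry is the one place scale interacts with power: informative
clones need one end in the unique window between repeat C and A1a (~12 kb
at scale 1), so desk-scale libraries shrink that window tenfold. The seeded
recovery test therefore simulates a deep (40×) library at scale 1, while
the zero-false-call property runs at desk scale where it is
coverage-independent. The fixture places repeat D 12 kb distal to A1b,
mirroring the proximal unique window; D consequently extends somewhat
beyond the printed end of the repeat block, a trade made so both repeats
have realistic unique flanks for end-pair and cloning logic.

Other defaults: Jct1 crossover offset 10 kb (mid-repeat) — any offset gives
the same band sizes and, away from the primer-target offsets, the same qPCR
counts; inversion crossover mid-repeat; band-class tolerance 5% (gel
resolution); progenitor classification thresholds 1.5 (H2) and 0.75 (H1) on
the 29:25 dosage ratio, bracketing the expected values 2, 1 and 0.5.

## Structure reconciliation

`reconcile_structure()` is a finite-grammar matcher, not a general
rearrangement solver. It parameterizes {reference, tandem duplication,
DUP-TRP/INV-DUP, DUP-TRP/INV-DUP + nested deletion, rolling-circle
quadruplication} from the profile's transition points and scores each
against the observed profile shape and junction multiset; the alternative
two-step recombination route to a quadruplication is CN-indistinguishable
from the rolling-circle model and is reported with a note (it requires two
events in separate generations) but never scored. Patterns outside the
grammar return no consistent structure rather than a best guess. Junctions
inherited from an H2 progenitor are flagged polymorphic and excluded from
event matching, mirroring how a benign inversion haplotype must not be
mistaken for rearrangement evidence.

## Known limitations

* Sequence-level operations run on synthetic sequences generated to match
  the architecture; the hg19 sequence itself is never required or shipped,
  so absolute restriction-fragment sizes are fixture constants, not genome
  predictions.
* A2/A3 boundaries are approximate (flagged in the fixture); the model
  treats them as annotation only, since no modeled event uses them as
  substrates.
* The rolling-circle builder abstracts the terminating switch as a proximal
  re-entry, which reproduces the published copy-number states and junction
  multiplicities but not every fine-scale feature of the one published
  quadruplication profile (which includes an additional copy-neutral
  segment).
* Inter-chromosomal insertions, genome-wide repeat discovery, recombination
  hotspot motif scanning and LD estimation are out of scope.
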