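# Seeded synthetic-data generators. Every generator is deterministic under a
# fixed config (same seed -> byte-identical output) and emits the truth it
# planted, so the callers can be tested end to end with no external data.

#' Simulation configuration
#'
#' Length-type parameters are given at locus scale 1 and are multiplied by
#' the locus scale where used.
#'
#' @param seed integer RNG seed.
#' @param fosmid_coverage fold clone coverage.
#' @param insert_range concordant fosmid insert range (bp, scale 1).
#' @param end_length fosmid end-read length (bp, scale 1).
#' @param read_length junction read length (bp; ~600 bp is the sequencing
#'   convention the junction truth emulates).
#' @param denovo_rate de novo point-mutation rate per sequenced bp
#'   (default 2 mutations per 15 kb).
#' @param acgh_spacing array probe spacing (bp, scale 1).
#' @param acgh_sd Gaussian noise sd on log2 ratios.
#' @return a `cgr_sim_config` list.
#' @export
sim_config <- function(seed = 1, fosmid_coverage = 10,
                       insert_range = c(32000, 48000), end_length = 500,
                       read_length = 600, denovo_rate = 2 / 15000,
                       acgh_spacing = 500, acgh_sd = 0.25) {
  stopifnot(seed == round(seed), fosmid_coverage > 0,
            insert_range[1] < insert_range[2], read_length >= 20,
            denovo_rate >= 0 && denovo_rate <= 1, acgh_spacing > 0)
  structure(list(seed = as.integer(seed), fosmid_coverage = fosmid_coverage,
                 insert_range = insert_range, end_length = end_length,
                 read_length = read_length, denovo_rate = denovo_rate,
                 acgh_spacing = acgh_spacing, acgh_sd = acgh_sd),
            class = "cgr_sim_config")
}

#' Generate a synthetic locus sequence with paralog structure
#'
#' I.i.d. uniform background sequence over the locus extent; each repeat
#' pair's right paralog is generated by copying the left and applying per-base
#' substitutions at rate `1 - identity` (reverse-complemented for inverted
#' pairs). The realized PSV truth of the middle (crossover-mediating) pair is
#' returned alongside the sequence.
#'
#' @param locus a `cgr_locus` (typically `plp1_locus(scale)` with a small
#'   scale).
#' @param cfg a [sim_config()].
#' @param pair pair whose PSV truth to report (default "A").
#' @return list with `sequence` (character), `psv_truth` (tibble `pos`, `a`,
#'   `b` in the left-paralog frame), `annotation` (BED-like tibble).
#' @export
make_locus_sequence <- function(locus, cfg = sim_config(), pair = "A") {
  reps <- locus$repeats
  if (any(reps$end - reps$start < 100)) {
    abort("repeat shorter than 100 bp at this scale: increase scale")
  }
  for (i in seq_len(nrow(locus$pairs))) {
    p <- pair_info(locus, locus$pairs$left[i])
    expected <- (1 - p$identity) * p$len
    if (p$identity < 1 && expected < 1) {
      abort(paste0("identity ", p$identity, " incompatible with repeat ",
                   "length ", p$len, ": expected PSVs < 1"))
    }
  }
  e0 <- locus$extent[1]
  n <- locus$extent[2] - e0
  with_seed(cfg$seed, {
    chars <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
    truth <- NULL
    for (i in seq_len(nrow(locus$pairs))) {
      p <- pair_info(locus, locus$pairs$left[i])
      left <- paste0(chars[(p$a1 - e0 + 1):(p$a2 - e0)], collapse = "")
      mut <- mutate_dna(left, 1 - p$identity)
      right <- if (locus$pairs$inverted[i]) revcomp(mut$seq) else mut$seq
      chars[(p$b1 - e0 + 1):(p$b1 - e0 + nchar(right))] <-
        strsplit(right, "")[[1]]
      if (locus$pairs$family[i] == pair || locus$pairs$left[i] == pair) {
        lc <- strsplit(left, "")[[1]]
        mc <- strsplit(mut$seq, "")[[1]]
        truth <- tibble(pos = mut$positions, a = lc[mut$positions],
                        b = mc[mut$positions])
      }
    }
    list(sequence = paste0(chars, collapse = ""),
         psv_truth = truth %||% tibble(pos = integer(), a = character(),
                                       b = character()),
         annotation = tibble(chrom = locus$chrom, start = reps$start,
                             end = reps$end, name = reps$name))
  })
}

build_event_allele <- function(locus, event) {
  switch(event$type,
    reference = reference_allele(locus),
    inversion = apply_inversion(locus, crossover = event$crossover),
    tandem_duplication = {
      al <- reference_allele(locus)
      v <- function(x) x - locus$extent[1]
      assemble_allele(
        list(extract_piece(al, 0, v(event$dup_end)),
             extract_piece(al, v(event$dup_start), allele_length(al))),
        list(junction_row("TD", event$dup_end, event$dup_start, "direct")),
        locus, provenance = list(event = "tandem_duplication"))
    },
    dup_trp_inv_dup = build_dup_trp_inv_dup(
      locus, trp_start = event$trp_start, dup_start = event$dup_start,
      jct1_crossover = event$jct1_crossover %||% NULL,
      progenitor = event$progenitor %||% "H1"),
    dup_trp_inv_dup_del = {
      al <- build_dup_trp_inv_dup(
        locus, trp_start = event$trp_start, dup_start = event$dup_start,
        jct1_crossover = event$jct1_crossover %||% NULL,
        progenitor = event$progenitor %||% "H1")
      idx <- which(al$segments$start <= event$deletion[1] &
                   al$segments$end >= event$deletion[2])
      apply_nested_deletion(al, idx[length(idx)], event$deletion)
    },
    quadruplication = build_rolling_circle_quadruplication(
      locus, circle = event$circle, rolled_length = event$rolled_length,
      termination_crossover = event$termination_crossover,
      progenitor = event$progenitor %||% "H1"),
    abort(paste0("unknown event type: ", event$type)))
}

#' Simulate a rearranged genome with planted truth
#'
#' Builds the requested event allele, generates the locus sequence, emits the
#' product sequence, and records per-junction truth including the realized
#' microhomology implied by the flanking sequences (computed from the
#' templates on both sides of each switch).
#'
#' @param locus a `cgr_locus`.
#' @param event list with `type` (one of `reference`, `inversion`,
#'   `tandem_duplication`, `dup_trp_inv_dup`, `dup_trp_inv_dup_del`,
#'   `quadruplication`) and its parameters.
#' @param cfg a [sim_config()].
#' @return list with `allele`, `sequence` (product), `reference` (locus
#'   sequence), `profile` (anchor-snapped), `junction_truth` (tibble).
#' @export
simulate_rearranged_genome <- function(locus, event, cfg = sim_config()) {
  allele <- build_event_allele(locus, event)
  genome <- make_locus_sequence(locus, cfg)
  emitted <- emit_sequence(allele, genome$sequence)
  truth <- junction_truth(allele, genome$sequence)
  list(allele = allele, sequence = emitted, reference = genome$sequence,
       psv_truth = genome$psv_truth,
       profile = copy_number_profile(allele, snap = TRUE),
       junction_truth = truth)
}

# product-orientation template context around a segment boundary
seq_after_boundary <- function(ref, e0, boundary, strand, n) {
  if (strand == "+") substr(ref, boundary - e0 + 1, boundary - e0 + n)
  else revcomp(substr(ref, max(1, boundary - e0 - n + 1), boundary - e0))
}
seq_before_boundary <- function(ref, e0, boundary, strand, n) {
  if (strand == "+") substr(ref, max(1, boundary - e0 - n + 1), boundary - e0)
  else revcomp(substr(ref, boundary - e0 + 1, boundary - e0 + n))
}

# expected microhomology at every junction of an allele, from the reference
# sequence: the switch is flanked by identical template context for
# (common suffix of upstream contexts) + (common prefix of downstream
# contexts) bases.
junction_truth <- function(allele, reference, window = 50) {
  seg <- allele$segments
  jn <- allele$junctions
  e0 <- allele$locus$extent[1]
  off <- segment_offsets(allele)
  if (nrow(jn) == 0) {
    return(tibble(label = character(), virtual_pos = numeric(),
                  microhomology_len = integer()))
  }
  out <- vector("list", nrow(jn))
  for (i in seq_len(nrow(jn))) {
    donor_strand <- seg$strand[i]
    donor_bnd <- if (donor_strand == "+") seg$end[i] else seg$start[i]
    acc_strand <- seg$strand[i + 1]
    acc_bnd <- if (acc_strand == "+") seg$start[i + 1] else seg$end[i + 1]
    k1 <- common_prefix_len(
      seq_after_boundary(reference, e0, donor_bnd, donor_strand, window),
      seq_after_boundary(reference, e0, acc_bnd, acc_strand, window))
    k2 <- common_suffix_len(
      seq_before_boundary(reference, e0, donor_bnd, donor_strand, window),
      seq_before_boundary(reference, e0, acc_bnd, acc_strand, window))
    out[[i]] <- tibble(label = jn$label[i], virtual_pos = off[i + 1],
                       microhomology_len = k1 + k2)
  }
  dplyr::bind_rows(out)
}

#' Simulate junction-spanning reads
#'
#' One read per junction, centered on the switch point, with de novo
#' mutations planted at the configured per-bp rate (Poisson) and recorded in
#' the truth.
#'
#' @param sim output of [simulate_rearranged_genome()].
#' @param cfg a [sim_config()].
#' @return tibble with `read_id`, `label`, `sequence`, `prox_flank`,
#'   `dist_flank` (reference templates for calling), `n_mutations`,
#'   `mutations` (list-column).
#' @export
simulate_junction_reads <- function(sim, cfg = sim_config()) {
  allele <- sim$allele
  jt <- sim$junction_truth
  L <- cfg$read_length
  half <- floor(L / 2)
  emitted <- sim$sequence
  seg <- allele$segments
  e0 <- allele$locus$extent[1]
  off <- segment_offsets(allele)
  with_seed(cfg$seed + 2L, {
    out <- vector("list", nrow(jt))
    for (i in seq_len(nrow(jt))) {
      v <- jt$virtual_pos[i]
      lo <- max(0, v - half); hi <- min(nchar(emitted), v + half)
      read <- substr(emitted, lo + 1, hi)
      # flanking templates, each at least as long as the read
      si <- max(which(off <= v)) - 1
      si <- min(si + 1, nrow(seg))  # segment following boundary v
      donor_i <- si - 1
      donor_bnd <- if (seg$strand[donor_i] == "+") seg$end[donor_i]
                   else seg$start[donor_i]
      acc_bnd <- if (seg$strand[si] == "+") seg$start[si] else seg$end[si]
      prox <- paste0(
        seq_before_boundary(sim$reference, e0, donor_bnd,
                            seg$strand[donor_i], v - lo),
        seq_after_boundary(sim$reference, e0, donor_bnd,
                           seg$strand[donor_i], nchar(read)))
      dist <- paste0(
        seq_before_boundary(sim$reference, e0, acc_bnd, seg$strand[si],
                            nchar(read)),
        seq_after_boundary(sim$reference, e0, acc_bnd, seg$strand[si],
                           hi - v))
      n_mut <- stats::rpois(1, cfg$denovo_rate * nchar(read))
      muts <- tibble(pos = integer(), type = character())
      if (n_mut > 0) {
        rc <- strsplit(read, "")[[1]]
        pos <- sample(seq(10, length(rc) - 10), n_mut)
        for (pp in pos) {
          rc[pp] <- sample(setdiff(c("A", "C", "G", "T"), rc[pp]), 1)
        }
        read <- paste0(rc, collapse = "")
        muts <- tibble(pos = pos, type = "substitution")
      }
      out[[i]] <- tibble(
        read_id = paste0("read_", i), label = jt$label[i],
        sequence = read,
        prox_flank = substr(prox, 1, nchar(read)),
        dist_flank = substr(dist, nchar(dist) - nchar(read) + 1, nchar(dist)),
        n_mutations = n_mut, mutations = list(muts))
    }
    dplyr::bind_rows(out)
  })
}

#' Simulate a fosmid end-pair library
#'
#' Uniform clone starts over each allele's product chromosome, insert sizes
#' uniform in the configured range, end orientations derived by mapping the
#' ends back to reference coordinates through the allele's segment map
#' (concordant clones map `+/-`).
#'
#' @param genotype a `cgr_allele` or list of alleles.
#' @param cfg a [sim_config()].
#' @param individual id recorded in the output.
#' @return BEDPE-like tibble (`chrom`, `start1`, `end1`, `strand1`, `start2`,
#'   `end2`, `strand2`, `clone`, `individual`).
#' @export
simulate_fosmid_pairs <- function(genotype, cfg = sim_config(),
                                  individual = "sim") {
  alleles <- as_genotype(genotype)
  locus <- alleles[[1]]$locus
  s <- locus$scale
  ins_rng <- cfg$insert_range * s
  eb <- max(20, round(cfg$end_length * s))
  if (ins_rng[2] >= min(vapply(alleles, allele_length, numeric(1)))) {
    abort("insert range larger than the allele")
  }
  with_seed(cfg$seed + 1L, {
    per_allele <- lapply(seq_along(alleles), function(ai) {
      al <- alleles[[ai]]
      L <- allele_length(al)
      n <- round(cfg$fosmid_coverage * L / mean(ins_rng))
      starts <- floor(stats::runif(n, 0, L - ins_rng[2] - 1))
      inserts <- round(stats::runif(n, ins_rng[1], ins_rng[2]))
      e1 <- map_ends(al, starts, eb, first = TRUE)
      e2 <- map_ends(al, starts + inserts - eb, eb, first = FALSE)
      ok <- !is.na(e1$start) & !is.na(e2$start)
      swap <- ok & e1$start > e2$start
      for (f in c("start", "end", "strand")) {
        tmp <- e1[[f]][swap]
        e1[[f]][swap] <- e2[[f]][swap]
        e2[[f]][swap] <- tmp
      }
      tibble(chrom = locus$chrom,
             start1 = e1$start[ok], end1 = e1$end[ok],
             strand1 = e1$strand[ok],
             start2 = e2$start[ok], end2 = e2$end[ok],
             strand2 = e2$strand[ok],
             clone = paste0(individual, "_a", ai, "_c", which(ok)),
             individual = individual)
    })
    dplyr::bind_rows(per_allele)
  })
}

# map fosmid ends (virtual intervals of length eb starting at v, vectorized)
# back to reference coordinates; second ends are sequenced inward, flipping
# strand. Ends spanning a junction are unmapped (NA).
map_ends <- function(allele, v, eb, first = TRUE) {
  seg <- allele$segments
  off <- segment_offsets(allele)
  i <- findInterval(v, off, rightmost.closed = TRUE)
  ok <- i >= 1 & i <= nrow(seg)
  ok[ok] <- (v[ok] + eb) <= off[i[ok] + 1]
  start <- end <- rep(NA_real_, length(v))
  strand <- rep(NA_character_, length(v))
  plus <- ok & seg$strand[pmax(i, 1)] == "+"
  minus <- ok & !plus
  start[plus] <- seg$start[i[plus]] + (v[plus] - off[i[plus]])
  end[plus] <- start[plus] + eb
  strand[plus] <- if (first) "+" else "-"
  end[minus] <- seg$end[i[minus]] - (v[minus] - off[i[minus]])
  start[minus] <- end[minus] - eb
  strand[minus] <- if (first) "-" else "+"
  list(start = start, end = end, strand = strand)
}

#' Simulate an aCGH probe table from a copy-number profile
#'
#' Probe log2 ratios in the hemizygous male convention
#' (`log2(state / 1)` plus Gaussian noise).
#'
#' @param profile a `cgr_profile`.
#' @param cfg a [sim_config()].
#' @param scale locus scale (probe spacing is `acgh_spacing * scale`).
#' @return tibble with `pos`, `log2_ratio`, `state` (truth).
#' @export
simulate_acgh <- function(profile, cfg = sim_config(), scale = 1) {
  spacing <- max(1, round(cfg$acgh_spacing * scale))
  lo <- min(profile$start); hi <- max(profile$end)
  pos <- seq(lo + floor(spacing / 2), hi - 1, by = spacing)
  state <- profile$state[findInterval(pos, profile$start)]
  with_seed(cfg$seed + 3L, {
    tibble(pos = pos,
           log2_ratio = log2(pmax(state, 2^-5)) +
             stats::rnorm(length(pos), 0, cfg$acgh_sd),
           state = state)
  })
}

#' Mean-shift changepoint segmentation of an aCGH probe table
#'
#' A deliberately simple sliding-window mean-shift detector (not a
#' reimplementation of any array pipeline): a changepoint is called between
#' probes where the difference of flanking window means exceeds `threshold`,
#' keeping only the locally strongest calls at least `min_seg` probes apart.
#'
#' @param acgh tibble from [simulate_acgh()].
#' @param min_seg minimum segment length in probes.
#' @param threshold minimum absolute mean shift (log2 units).
#' @return tibble with `index` (probe index left of the change), `pos`
#'   (genomic boundary), `shift`.
#' @export
segment_acgh <- function(acgh, min_seg = 5, threshold = 0.4) {
  y <- acgh$log2_ratio
  n <- length(y)
  w <- min_seg
  if (n < 2 * w + 1) abort("too few probes to segment")
  shift <- rep(NA_real_, n)
  for (i in seq(w + 1, n - w + 1)) {
    shift[i] <- mean(y[i:(i + w - 1)]) - mean(y[(i - w):(i - 1)])
  }
  cand <- which(!is.na(shift) & abs(shift) >= threshold)
  cand <- cand[order(-abs(shift[cand]))]
  kept <- integer()
  for (i in cand) {
    if (all(abs(kept - i) >= min_seg)) kept <- c(kept, i)
  }
  kept <- sort(kept)
  tibble(index = kept - 1,
         pos = (acgh$pos[pmax(kept - 1, 1)] + acgh$pos[kept]) / 2,
         shift = shift[kept])
}

#' Simulate a digital PCR experiment
#'
#' Poisson droplet partitioning of a junction assay and the RNase P
#' reference; concentrations are estimated from the negative-droplet
#' fraction, and copies per genome via [dpcr_copies_per_genome()].
#'
#' @param true_copies_per_genome planted junction copies per genome.
#' @param cfg a [sim_config()].
#' @param rnasep_conc true reference concentration (copies/uL).
#' @param n_droplets droplets per assay.
#' @param droplet_volume droplet volume (uL).
#' @return one-row tibble: estimated `jct_conc`, `rnasep_conc`,
#'   `copies_per_genome`.
#' @export
simulate_dpcr <- function(true_copies_per_genome, cfg = sim_config(),
                          rnasep_conc = 400, n_droplets = 20000,
                          droplet_volume = 7.55e-4) {
  true_jct <- true_copies_per_genome * rnasep_conc / 2
  with_seed(cfg$seed + 4L, {
    est <- function(conc) {
      p_pos <- 1 - exp(-conc * droplet_volume)
      k <- stats::rbinom(1, n_droplets, p_pos)
      -log(1 - k / n_droplets) / droplet_volume
    }
    jct <- est(true_jct); rp <- est(rnasep_conc)
    tibble(jct_conc = jct, rnasep_conc = rp,
           copies_per_genome = dpcr_copies_per_genome(jct, rp))
  })
}

#' Recover the event type of an observed rearrangement
#'
#' Convenience wrapper: anchor-snapped profile plus event junction multiset
#' into [reconcile_structure()], returning the consistent grammar members.
#'
#' @param allele a `cgr_allele` (or a profile + junction multiset via the
#'   underlying function).
#' @return character vector of consistent model names.
#' @export
recover_event_type <- function(allele) {
  res <- reconcile_structure(copy_number_profile(allele, snap = TRUE),
                             junction_multiset(allele), allele$locus)
  res$model[which(res$consistent)]
}
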