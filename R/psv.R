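# Paralogous sequence variants (PSVs): fixed differences between two repeat
# paralogs, the only markers that can localize a crossover inside
# near-identical low-copy repeats.

#' Call PSVs between two repeat paralogs
#'
#' Aligns the paralogs and reports every substitution column as a PSV in the
#' paralog-A coordinate frame. Equal-length paralogs that meet the identity
#' floor are compared column-wise directly (the generative model for
#' simulated paralogs is substitution-only); otherwise a global pairwise
#' alignment with affine gaps is used (match 1, mismatch -2, gap open -5,
#' extend -1) and indel columns are recorded separately as length-variant
#' tracts, not PSVs.
#'
#' @param paralog_a,paralog_b sequences (character), both >= 100 bp. If the
#'   paralogs lie in inverted orientation on the reference, pass the right
#'   paralog reverse-complemented so both read in the shared frame.
#' @param min_identity identity floor below which the pair is considered
#'   unalignable (default 0.8).
#' @return a `cgr_psv_map`: tibble with `pos` (1-based position in the A
#'   frame), `a`, `b`; attribute `indels` holds length-variant tracts.
#' @export
call_psvs <- function(paralog_a, paralog_b, min_identity = 0.8) {
  a <- toupper(paralog_a); b <- toupper(paralog_b)
  if (nchar(a) < 100 || nchar(b) < 100) abort("paralogs must be >= 100 bp")
  indels <- tibble(pos = integer(), length = integer(), in_paralog = character())
  if (nchar(a) == nchar(b)) {
    ac <- strsplit(a, "")[[1]]; bc <- strsplit(b, "")[[1]]
    mism <- which(ac != bc)
    if (1 - length(mism) / nchar(a) >= min_identity) {
      out <- tibble(pos = mism, a = ac[mism], b = bc[mism])
      return(structure(out, class = c("cgr_psv_map", class(out)),
                       indels = indels))
    }
  }
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(a), Biostrings::DNAString(b), type = "global",
    substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
      match = 1, mismatch = -2, baseOnly = TRUE),
    gapOpening = 5, gapExtension = 1)
  pa <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  pb <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  non_gap <- pa != "-" & pb != "-"
  ident <- sum(pa == pb & non_gap) / sum(non_gap)
  if (ident < min_identity) {
    abort(sprintf("paralogs unalignable at the %.0f%% identity floor (%.1f%%)",
                  100 * min_identity, 100 * ident))
  }
  apos <- cumsum(pa != "-")
  mism <- which(non_gap & pa != pb)
  out <- tibble(pos = apos[mism], a = pa[mism], b = pb[mism])
  gap_runs <- rle(!non_gap)
  if (any(gap_runs$values)) {
    ends <- cumsum(gap_runs$lengths)
    starts <- ends - gap_runs$lengths + 1
    gi <- which(gap_runs$values)
    indels <- tibble(pos = apos[starts[gi]],
                     length = gap_runs$lengths[gi],
                     in_paralog = ifelse(pa[starts[gi]] == "-", "a", "b"))
  }
  structure(out, class = c("cgr_psv_map", class(out)), indels = indels)
}

#' Map the crossover interval in a chimeric sequence
#'
#' Genotypes the chimera at every PSV and localizes the template switch: the
#' maximal interval bounded by the last PSV matching paralog A and the first
#' matching paralog B (or the reverse, direction B->A). PSVs outside the
#' interval must be consistent with a single switch; isolated inconsistent
#' PSVs are reported as gene-conversion-like secondary candidates, and >= 2
#' consecutive inconsistent PSVs yield a multi-switch report instead of a
#' silently merged call. When the bounding PSVs are farther apart than
#' `max_resolvable`, the call is labeled unresolvable (a PSV desert).
#'
#' @param chimera chimeric sequence in the shared paralog frame (same length
#'   as paralog A for the column-wise frame; otherwise it is aligned to A).
#' @param paralog_a,paralog_b the two paralogs.
#' @param psvs optional precomputed [call_psvs()] map.
#' @param max_resolvable report ceiling in bp (default 8000): wider intervals
#'   are labeled unresolvable.
#' @return a `cgr_crossover` list: `last_a`, `first_b`, `identity_block_len`,
#'   `direction`, `unresolvable`, `secondary` (tibble of inconsistent PSVs),
#'   `multi_switch`.
#' @export
map_crossover <- function(chimera, paralog_a, paralog_b, psvs = NULL,
                          max_resolvable = 8000) {
  psvs <- psvs %||% call_psvs(paralog_a, paralog_b)
  if (nrow(psvs) == 0) abort("no PSVs between the paralogs: switch unmappable")
  ch <- toupper(chimera)
  cc <- strsplit(ch, "")[[1]]
  if (length(cc) < max(psvs$pos)) abort("chimera shorter than the PSV frame")
  state <- ifelse(cc[psvs$pos] == psvs$a, "A",
                  ifelse(cc[psvs$pos] == psvs$b, "B", "?"))
  inf <- state != "?"
  pos <- psvs$pos[inf]; st <- state[inf]
  if (length(st) == 0) abort("no informative PSVs in the chimera")
  if (all(st == "A") || all(st == "B")) {
    abort("not chimeric: chimera matches a single paralog at every PSV")
  }
  # best single-switch boundary: minimize PSVs inconsistent with
  # first-state-then-last-state; direction by which order fits better
  n_inf <- length(st)
  cost_dir <- function(first_state, last_state) {
    costs <- vapply(0:n_inf, function(b) {
      sum(st[seq_len(b)] == last_state) +
        sum(st[setdiff(seq_len(n_inf), seq_len(b))] == first_state)
    }, numeric(1))
    b <- which.min(costs) - 1
    list(b = b, cost = costs[b + 1])
  }
  ab <- cost_dir("A", "B"); ba <- cost_dir("B", "A")
  if (ab$cost <= ba$cost) {
    direction <- "A->B"; first_state <- "A"; last_state <- "B"; b <- ab$b
  } else {
    direction <- "B->A"; first_state <- "B"; last_state <- "A"; b <- ba$b
  }
  inconsistent <- which(
    (seq_len(n_inf) <= b & st == last_state) |
    (seq_len(n_inf) > b & st == first_state))
  # >= 2 adjacent inconsistent PSVs open a new block: multi-switch report
  if (length(inconsistent) >= 2 && any(diff(inconsistent) == 1)) {
    return(structure(list(
      multi_switch = TRUE, direction = direction,
      secondary = tibble(pos = pos[inconsistent], state = st[inconsistent]),
      note = ">=2 consecutive inconsistent PSVs: multi-switch or gene conversion"),
      class = "cgr_crossover"))
  }
  consistent_first <- which(seq_len(n_inf) <= b & st == first_state)
  consistent_last <- which(seq_len(n_inf) > b & st == last_state)
  if (length(consistent_first) == 0 || length(consistent_last) == 0) {
    abort("not chimeric: no consistent switch between the paralogs")
  }
  last_first <- max(consistent_first)
  first_last <- min(consistent_last)
  la <- pos[last_first]; fb <- pos[first_last]
  block <- fb - la - 1
  structure(list(
    multi_switch = FALSE,
    last_a = if (direction == "A->B") la else fb,
    first_b = if (direction == "A->B") fb else la,
    switch_interval = c(la, fb),
    identity_block_len = block,
    direction = direction,
    unresolvable = block > max_resolvable,
    secondary = tibble(pos = pos[inconsistent], state = st[inconsistent])),
    class = "cgr_crossover")
}

#' @export
print.cgr_crossover <- function(x, ...) {
  if (isTRUE(x$multi_switch)) {
    cat("<crossover> multi-switch / gene-conversion pattern (",
        nrow(x$secondary), " inconsistent PSVs)\n", sep = "")
  } else {
    cat("<crossover> ", x$direction, " between PSVs ", x$switch_interval[1],
        " and ", x$switch_interval[2], " (identity block ",
        x$identity_block_len, " bp",
        if (x$unresolvable) "; unresolvable PSV desert", ")\n", sep = "")
  }
  invisible(x)
}

#' Tidy a crossover call
#' @param x a `cgr_crossover`.
#' @param ... unused.
#' @return one-row tibble.
#' @export
tidy.cgr_crossover <- function(x, ...) {
  if (isTRUE(x$multi_switch)) {
    tibble(multi_switch = TRUE, direction = x$direction,
           identity_block_len = NA_real_, unresolvable = NA,
           n_secondary = nrow(x$secondary))
  } else {
    tibble(multi_switch = FALSE, direction = x$direction,
           last_a = x$last_a, first_b = x$first_b,
           identity_block_len = x$identity_block_len,
           unresolvable = x$unresolvable, n_secondary = nrow(x$secondary))
  }
}

#' Predict PSV-specific PCR amplicon classes
#'
#' A genotyping assay with paralog-specific forward and reverse primers at
#' two informative PSV offsets of the repeat frame: AA amplifies an intact A
#' paralog, BB an intact B paralog, and AB/BA the two reciprocal chimeras
#' created by an inversion crossover between the primer sites. The product
#' chromosome of each allele is walked and every forward/reverse primer-site
#' pair linked within `max_amplicon` bp yields an amplicon class.
#'
#' @param genotype a `cgr_allele` or list of alleles.
#' @param forward_offset,reverse_offset primer PSV offsets within the aligned
#'   repeat frame (forward proximal, reverse distal).
#' @param pair repeat pair (default "A").
#' @param max_amplicon maximum amplicon length (default 2x the repeat
#'   length).
#' @param psvs optional PSV map (A frame): when supplied, the primer offsets
#'   must be PSV-informative positions.
#' @return tibble with `class` (AA/BB/AB/BA) and `present`.
#' @export
predict_psv_pcr <- function(genotype, forward_offset = NULL,
                            reverse_offset = NULL, pair = "A",
                            max_amplicon = NULL, psvs = NULL) {
  alleles <- as_genotype(genotype)
  locus <- alleles[[1]]$locus
  p <- pair_info(locus, pair)
  forward_offset <- forward_offset %||% round(0.02 * p$len)
  reverse_offset <- reverse_offset %||% round(0.98 * p$len)
  if (!is.null(psvs) &&
      !all(c(forward_offset, reverse_offset) %in% psvs$pos)) {
    abort("primer positions are not PSV-informative")
  }
  if (forward_offset >= reverse_offset) {
    abort("forward primer offset must be proximal to the reverse offset")
  }
  max_amplicon <- max_amplicon %||% (2 * p$len)
  sites <- tibble(
    ref = c(p$a1 + forward_offset, p$a1 + reverse_offset,
            p$b2 - forward_offset, p$b2 - reverse_offset),
    role = c("F", "R", "F", "R"),
    paralog = c("A", "A", "B", "B"))
  classes <- character(0)
  for (al in alleles) {
    occ <- purrr::pmap(sites, function(ref, role, paralog) {
      v <- virtual_occurrences(al, ref)
      if (length(v)) tibble(virtual = v, role = role, paralog = paralog)
    })
    occ <- dplyr::bind_rows(occ)
    if (nrow(occ) < 2) next
    occ <- dplyr::arrange(occ, .data$virtual)
    i <- 1
    while (i < nrow(occ)) {
      if (occ$role[i] != occ$role[i + 1] &&
          occ$virtual[i + 1] - occ$virtual[i] <= max_amplicon) {
        f <- if (occ$role[i] == "F") i else i + 1
        r <- if (occ$role[i] == "R") i else i + 1
        classes <- c(classes, paste0(occ$paralog[f], occ$paralog[r]))
        i <- i + 2
      } else i <- i + 1
    }
  }
  tibble(class = c("AA", "BB", "AB", "BA")) |>
    dplyr::mutate(present = .data$class %in% classes)
}

#' Plan paralog-spanning cloning amplicons
#'
#' Designs the four overlapping long-range amplicons (two per paralog) that
#' tile a repeat pair, each anchored by one primer in unique flanking
#' sequence, so that cloned products can be assigned to a paralog and
#' genotyped at PSVs.
#'
#' @param locus a `cgr_locus`.
#' @param pair repeat pair (default "A").
#' @param anchor_bp unique-flank anchor length (scaled with the locus).
#' @param overlap_bp overlap between the two amplicons of one paralog.
#' @return tibble with `amplicon` (1-4), `paralog`, `start`, `end`, `length`,
#'   `anchor_side`.
#' @export
plan_lcr_cloning <- function(locus, pair = "A", anchor_bp = NULL,
                             overlap_bp = NULL) {
  p <- pair_info(locus, pair)
  anchor_bp <- anchor_bp %||% round(2000 * locus$scale)
  overlap_bp <- overlap_bp %||% round(1000 * locus$scale)
  reps <- locus$repeats
  in_repeat <- function(iv) {
    any(iv[1] < reps$end & iv[2] > reps$start)
  }
  amps <- list(); k <- 0
  for (nm in c(p$left_name, p$right_name)) {
    r <- repeat_interval(locus, nm)
    half <- floor((r[2] - r[1]) / 2)
    left_anchor <- c(r[1] - anchor_bp, r[1])
    right_anchor <- c(r[2], r[2] + anchor_bp)
    if (in_repeat(left_anchor) || in_repeat(right_anchor)) {
      abort(paste0("repeat ", nm, " lacks a unique flank for anchored ",
                   "amplification"))
    }
    k <- k + 1
    amps[[k]] <- tibble(amplicon = k, paralog = nm,
                        start = r[1] - anchor_bp,
                        end = r[1] + half + overlap_bp,
                        anchor_side = "proximal")
    k <- k + 1
    amps[[k]] <- tibble(amplicon = k, paralog = nm,
                        start = r[1] + half - overlap_bp,
                        end = r[2] + anchor_bp,
                        anchor_side = "distal")
  }
  out <- dplyr::bind_rows(amps)
  dplyr::mutate(out, length = .data$end - .data$start)
}
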