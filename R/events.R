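# Event builders: each returns a cgr_allele whose segment/junction list is the
# constructive model of one rearrangement product. Events can be applied to a
# locus (acting on the reference chromosome) or composed on an existing allele
# (acting on its product chromosome), which is how products arising on the
# inverted (H2) structural haplotype are modeled.

# Assemble a product allele from an ordered list of extracted pieces and the
# junction rows between them. Pieces are lists with $segments and $junctions
# (junctions inherited from the template crossed during extraction). Abutting
# same-strand neighbours are merged and their junction row dropped: such an
# adjacency has been restored to reference contiguity (e.g. re-inverting an
# inversion), so no physical junction exists there.
assemble_allele <- function(pieces, between, locus, provenance) {
  segs <- list(); juncs <- list()
  for (i in seq_along(pieces)) {
    p <- pieces[[i]]
    ns <- nrow(p$segments)
    for (k in seq_len(ns)) {
      segs[[length(segs) + 1]] <- p$segments[k, ]
      if (k < ns) juncs[[length(juncs) + 1]] <- p$junctions[k, ]
    }
    if (i < length(pieces)) juncs[[length(juncs) + 1]] <- between[[i]]
  }
  seg <- dplyr::bind_rows(segs)
  jn <- if (length(juncs)) dplyr::bind_rows(juncs) else empty_junctions()
  # merge pass
  if (nrow(seg) > 1) {
    keep_seg <- rep(TRUE, nrow(seg)); keep_jn <- rep(TRUE, nrow(jn))
    j <- 1
    for (i in seq(2, nrow(seg))) {
      prev <- max(which(keep_seg[seq_len(i - 1)]))
      same <- seg$strand[prev] == seg$strand[i]
      abut <- (seg$strand[i] == "+" && seg$end[prev] == seg$start[i]) ||
              (seg$strand[i] == "-" && seg$start[prev] == seg$end[i])
      if (same && abut) {
        if (seg$strand[i] == "+") seg$end[prev] <- seg$end[i]
        else seg$start[prev] <- seg$start[i]
        keep_seg[i] <- FALSE
        keep_jn[i - 1] <- FALSE
      }
      j <- j + 1
    }
    seg <- seg[keep_seg, ]
    jn <- jn[keep_jn, ]
  }
  new_cgr_allele(seg, jn, locus = locus, provenance = provenance)
}

# extract a virtual interval together with the template junctions it crosses
extract_piece <- function(allele, vfrom, vto, orientation = "+") {
  segs <- extract_virtual(allele, vfrom, vto, orientation)
  off <- segment_offsets(allele)
  inner <- off[-c(1, length(off))]
  crossed <- which(inner > vfrom & inner < vto)
  jn <- allele$junctions[crossed, ]
  if (orientation == "-") jn <- jn[rev(seq_len(nrow(jn))), ]
  list(segments = segs, junctions = jn)
}

junction_row <- function(label, left_pos, right_pos, orientation,
                         in_repeat = NA_character_, polymorphic = FALSE) {
  tibble(label = label, left_pos = left_pos, right_pos = right_pos,
         orientation = orientation, in_repeat = in_repeat,
         polymorphic = polymorphic)
}

as_allele <- function(x) {
  if (inherits(x, "cgr_allele")) x
  else if (inherits(x, "cgr_locus")) reference_allele(x)
  else abort("expected a cgr_locus or cgr_allele")
}

check_crossover <- function(p, crossover, what = "crossover") {
  if (crossover <= 0 || crossover >= p$len) {
    abort(paste0(what, " (", crossover,
                 ") outside the alignable repeat region [1, ",
                 p$len - 1, ") of ", p$left_name, "/", p$right_name))
  }
}

#' Apply a NAHR inversion between an inverted repeat pair
#'
#' Models the ectopic crossover between the two paralogs of an inverted
#' repeat pair: the spacer between the repeats is reverse-complemented and
#' both repeats become reciprocal chimeras switching paralog at the crossover
#' offset. The event is copy-number neutral. Applying the same inversion twice
#' restores the input (involution). The two chimeric-repeat junctions are
#' flagged `polymorphic`, distinguishing the balanced structural haplotype
#' from pathogenic event junctions.
#'
#' @param x a `cgr_locus` (acts on the reference) or a `cgr_allele`.
#' @param pair pair family name (default the "A" pair, A1a/A1b).
#' @param crossover offset (bp) of the strand switch within the aligned
#'   repeat frame, measured from the left repeat's proximal edge.
#' @param locus locus model (required when `x` is an allele built on another
#'   locus; defaults to `x$locus` / `x`).
#' @return a `cgr_allele` (the H2 haplotype when applied to the reference).
#' @export
apply_inversion <- function(x, pair = "A", crossover = NULL, locus = NULL) {
  allele <- as_allele(x)
  locus <- locus %||% allele$locus
  p <- pair_info(locus, pair)
  crossover <- crossover %||% round(p$len / 2)
  check_crossover(p, crossover)
  xa <- p$a1 + crossover   # boundary in the left repeat
  xb <- p$b2 - crossover   # aligned boundary in the right (inverted) repeat
  va <- ref_to_virtual(allele, xa)
  vb <- ref_to_virtual(allele, xb)
  v_lo <- min(c(va, vb)); v_hi <- max(c(va, vb))
  if (v_lo >= v_hi) abort("inversion crossover maps to an empty interval")
  total <- allele_length(allele)
  pieces <- list(
    extract_piece(allele, 0, v_lo),
    extract_piece(allele, v_lo, v_hi, orientation = "-"),
    extract_piece(allele, v_hi, total))
  hap <- if (identical(allele$provenance$haplotype, "H2")) "H1" else "H2"
  between <- list(
    junction_row("inv_left", xa, xb, "inverted",
                 in_repeat = p$left_name, polymorphic = TRUE),
    junction_row("inv_right", xa, xb, "inverted",
                 in_repeat = p$right_name, polymorphic = TRUE))
  assemble_allele(pieces, between, locus,
                  provenance = list(event = "inversion", pair = pair,
                                    crossover = crossover, haplotype = hap))
}

#' Construct a DUP-TRP/INV-DUP allele
#'
#' Builds the duplication - inverted triplication - duplication product: a
#' direct copy from the extent start through the duplicated region into the
#' distal repeat up to the Jct1 template switch, an inverted copy back
#' through the spacer and the triplicated region to `trp_start` (Jct1,
#' homology-driven, inside the repeat pair), then Jct2 joining the inverted
#' copy to a direct copy from `dup_start` onwards. The derived copy-number
#' profile has exactly 4 transitions: 1->2 at `dup_start`, 2->3 at
#' `trp_start`, 3->2 at the canonical triplication endpoint and 2->1 at the
#' canonical duplication endpoint (anchor-snapped reporting; the raw coverage
#' transitions lie inside the repeats at the Jct1 crossover offset).
#'
#' @param locus a `cgr_locus`.
#' @param trp_start 0-based proximal triplication transition. Use
#'   [from_printed()] to convert printed 1-based positions.
#' @param dup_start 0-based proximal duplication transition.
#' @param jct1_crossover Jct1 template-switch offset within the aligned repeat
#'   frame (default: half the scaled mid-repeat, ~10 kb at scale 1).
#' @param progenitor `"H1"` (reference) or `"H2"` (inversion) structural
#'   haplotype the rearrangement arose on. The progenitor changes which
#'   chimeric repeats flank Jct1 (hence Southern dosage) but not the
#'   copy-number profile.
#' @param pair mediating repeat pair (default "A").
#' @param inversion_crossover crossover used to build the H2 progenitor.
#' @return a `cgr_allele`.
#' @export
build_dup_trp_inv_dup <- function(locus, trp_start, dup_start,
                                  jct1_crossover = NULL,
                                  progenitor = c("H1", "H2"),
                                  pair = "A", inversion_crossover = NULL) {
  progenitor <- match.arg(progenitor)
  p <- pair_info(locus, pair)
  jct1_crossover <- jct1_crossover %||% round(10000 * locus$scale)
  check_crossover(p, jct1_crossover, "jct1_crossover")
  trp_end <- locus$anchors$trp_end
  if (!(dup_start <= trp_start && trp_start < trp_end)) {
    abort(paste0("ordering violation: need dup_start <= trp_start < ",
                 "canonical triplication endpoint (",
                 to_printed(trp_end), ")"))
  }
  prog <- if (progenitor == "H2") {
    apply_inversion(locus, pair = pair, crossover = inversion_crossover)
  } else reference_allele(locus)
  e0 <- locus$extent[1]
  # product breakpoints in the progenitor frame; all lie outside the flipped
  # interval (or inside the repeats, where the frame geometry is unchanged),
  # so progenitor virtual position = reference offset.
  v <- function(pos) pos - e0
  u <- jct1_crossover
  total <- allele_length(prog)
  pieces <- list(
    extract_piece(prog, 0, v(p$b2 - u)),
    extract_piece(prog, v(trp_start), v(p$a1 + u), orientation = "-"),
    extract_piece(prog, v(dup_start), total))
  between <- list(
    junction_row("Jct1", p$b2 - u, p$a1 + u, "inverted",
                 in_repeat = paste0(p$left_name, "/", p$right_name)),
    junction_row("Jct2", trp_start, dup_start, "inverted"))
  assemble_allele(pieces, between, locus,
                  provenance = list(event = "dup_trp_inv_dup",
                                    trp_start = trp_start,
                                    dup_start = dup_start,
                                    jct1_crossover = u,
                                    progenitor = progenitor))
}

#' Delete an interval from one duplicated copy of an allele
#'
#' Models a nested deletion on one copy of a duplicated region: the chosen
#' segment copy loses `interval`, one additional junction is created, and the
#' copy number over the interval drops by one (producing the copy-number
#' neutral segments seen inside some duplications).
#'
#' @param allele a `cgr_allele`.
#' @param copy_index row index of the segment copy carrying the deletion.
#' @param interval length-2 numeric, 0-based half-open interval to delete;
#'   must be strictly inside the chosen copy's source.
#' @return a `cgr_allele` with one more junction.
#' @export
apply_nested_deletion <- function(allele, copy_index, interval) {
  seg <- allele$segments
  if (copy_index < 1 || copy_index > nrow(seg)) abort("no such segment copy")
  if (interval[2] - interval[1] < 1) abort("deletion interval is empty")
  s <- seg[copy_index, ]
  if (!(interval[1] >= s$start && interval[2] <= s$end)) {
    abort("interval not contained in the chosen copy")
  }
  off <- segment_offsets(allele)
  v0 <- off[copy_index]
  if (s$strand == "+") {
    v_lo <- v0 + (interval[1] - s$start); v_hi <- v0 + (interval[2] - s$start)
  } else {
    v_lo <- v0 + (s$end - interval[2]); v_hi <- v0 + (s$end - interval[1])
  }
  total <- allele_length(allele)
  pieces <- list(extract_piece(allele, 0, v_lo),
                 extract_piece(allele, v_hi, total))
  between <- list(junction_row("deletion", interval[1], interval[2], "direct"))
  prov <- allele$provenance
  prov$event <- paste0(prov$event, "+nested_deletion")
  prov$deletion <- interval
  assemble_allele(pieces, between, allele$locus, provenance = prov)
}

#' Construct a rolling-circle quadruplication allele
#'
#' Models higher-order amplification by rolling-circle replication: a
#' template switch at the distal circle boundary re-invades the proximal
#' boundary (the circle-establishing junction), replication traverses the
#' circularized segment repeatedly, and a final template switch (the
#' terminating junction) exits to `termination_crossover`. With
#' `rolled_length` just under two full circle lengths the establishing
#' junction is present in two copies and the terminating junction in one;
#' the region covered by both traversals is quadruplicated over the
#' duplicated background and the trailing shortfall region (length
#' `circle_length - rolled_length %% circle_length`) is triplicated.
#'
#' @param locus a `cgr_locus`.
#' @param circle length-2 numeric, 0-based half-open circularized interval.
#' @param rolled_length total bp replicated around the circle after its
#'   establishment; must be >= the circle length (shorter rolls are a plain
#'   tandem event and are rejected with that diagnosis).
#' @param termination_crossover 0-based boundary the terminating switch exits
#'   to; must be proximal to the circle (that re-entry is what duplicates the
#'   background).
#' @param progenitor structural haplotype, as in [build_dup_trp_inv_dup()].
#' @param establishing_label,terminating_label junction labels.
#' @param pair mediating repeat pair used for an H2 progenitor.
#' @param inversion_crossover crossover used to build the H2 progenitor.
#' @return a `cgr_allele`.
#' @export
build_rolling_circle_quadruplication <- function(locus, circle, rolled_length,
    termination_crossover, progenitor = c("H1", "H2"),
    establishing_label = "FoSTeS2/3", terminating_label = "FoSTeS1",
    pair = "A", inversion_crossover = NULL) {
  progenitor <- match.arg(progenitor)
  c1 <- circle[1]; c2 <- circle[2]
  clen <- c2 - c1
  if (clen < 1) abort("empty circle interval")
  if (c1 < locus$extent[1] || c2 > locus$extent[2]) {
    abort("circle outside locus extent")
  }
  if (rolled_length <= 0) abort("rolled_length must be positive")
  if (rolled_length < clen) {
    abort(paste0("rolled_length (", rolled_length, ") is shorter than the ",
                 "circle (", clen, "): no amplification beyond a plain ",
                 "tandem event"))
  }
  if (termination_crossover >= c1) {
    abort("termination_crossover must be proximal to the circle")
  }
  prog <- if (progenitor == "H2") {
    apply_inversion(locus, pair = pair, crossover = inversion_crossover)
  } else reference_allele(locus)
  e0 <- locus$extent[1]
  v <- function(pos) pos - e0
  n_traversals <- ceiling(rolled_length / clen)
  partial <- rolled_length %% clen
  total <- allele_length(prog)
  pieces <- list(extract_piece(prog, 0, v(c2)))
  between <- list()
  for (t in seq_len(n_traversals)) {
    hi <- if (t == n_traversals && partial > 0) c1 + partial else c2
    between[[length(between) + 1]] <-
      junction_row(establishing_label, c2, c1, "direct")
    pieces[[length(pieces) + 1]] <- extract_piece(prog, v(c1), v(hi))
  }
  term_from <- if (partial > 0) c1 + partial else c2
  between[[length(between) + 1]] <-
    junction_row(terminating_label, term_from, termination_crossover, "direct")
  pieces[[length(pieces) + 1]] <-
    extract_piece(prog, v(termination_crossover), total)
  assemble_allele(pieces, between, locus,
                  provenance = list(event = "rolling_circle_quadruplication",
                                    circle = circle,
                                    rolled_length = rolled_length,
                                    termination_crossover = termination_crossover,
                                    n_traversals = n_traversals,
                                    progenitor = progenitor))
}

#' Junction multiset of an allele
#'
#' @param allele a `cgr_allele`.
#' @param event_only drop junctions flagged as polymorphic structural
#'   haplotype junctions (inherited from an H2 progenitor)?
#' @return tibble with `label`, `orientation`, `in_repeat`, `multiplicity`.
#' @export
junction_multiset <- function(allele, event_only = TRUE) {
  jn <- allele$junctions
  if (event_only && nrow(jn)) jn <- jn[!jn$polymorphic, ]
  if (!nrow(jn)) {
    return(tibble(label = character(), orientation = character(),
                  in_repeat = character(), multiplicity = integer()))
  }
  dplyr::count(jn, .data$label, .data$orientation, .data$in_repeat,
               name = "multiplicity")
}
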