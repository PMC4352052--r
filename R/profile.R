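# Copy-number profiles: piecewise-constant integer coverage of the reference
# frame by allele segments (hemizygous male convention: the reference allele
# has state 1 everywhere).

#' Derive the copy-number profile of an allele
#'
#' Computes the reference coverage of the allele's segments as a minimal
#' piecewise-constant profile. Raw coverage places the distal transitions of
#' repeat-mediated products *inside* the mediating repeats (at the Jct1
#' crossover offset); because hybridization arrays cannot resolve positions
#' within near-identical paralogs, reported profiles conventionally place
#' those transitions at the canonical repeat-edge anchors. `snap = TRUE`
#' moves any transition falling strictly inside a mediating-pair repeat to
#' that repeat's anchor edge (left repeat -> `trp_end`, right repeat ->
#' `dup_end`), reproducing printed endpoint arithmetic.
#'
#' @param allele a `cgr_allele` (or list of alleles, whose coverages sum).
#' @param snap snap in-repeat transitions to the canonical anchors?
#' @param pair mediating pair used for snapping.
#' @return a `cgr_profile` tibble with columns `start`, `end`, `state`.
#' @export
copy_number_profile <- function(allele, snap = FALSE, pair = "A") {
  alleles <- if (inherits(allele, "cgr_allele")) list(allele) else allele
  locus <- alleles[[1]]$locus
  seg <- dplyr::bind_rows(lapply(alleles, function(a) a$segments))
  deltas <- tibble(pos = c(seg$start, seg$end),
                   delta = rep(c(1, -1), each = nrow(seg)))
  if (snap) {
    p <- pair_info(locus, pair)
    in_left <- deltas$pos > p$a1 & deltas$pos < p$a2
    in_right <- deltas$pos > p$b1 & deltas$pos < p$b2
    deltas$pos[in_left] <- locus$anchors$trp_end
    deltas$pos[in_right] <- locus$anchors$dup_end
  }
  deltas <- deltas |>
    dplyr::group_by(.data$pos) |>
    dplyr::summarise(delta = sum(.data$delta)) |>
    dplyr::filter(.data$delta != 0) |>
    dplyr::arrange(.data$pos)
  ext <- locus$extent
  bnd <- sort(unique(c(ext, deltas$pos)))
  bnd <- bnd[bnd >= ext[1] & bnd <= ext[2]]
  starts <- bnd[-length(bnd)]
  st <- vapply(starts, function(s) sum(deltas$delta[deltas$pos <= s]),
               numeric(1))
  prof <- tibble(start = starts, end = bnd[-1], state = st)
  # minimal representation: merge equal-adjacent
  prof$grp <- cumsum(c(TRUE, prof$state[-1] != prof$state[-nrow(prof)]))
  prof <- prof |>
    dplyr::group_by(.data$grp) |>
    dplyr::summarise(start = min(.data$start), end = max(.data$end),
                     state = .data$state[1]) |>
    dplyr::select("start", "end", "state")
  prof <- structure(prof, class = c("cgr_profile", class(prof)))
  attr(prof, "chrom") <- locus$chrom
  prof
}

#' Copy-number transitions of a profile
#'
#' @param profile a `cgr_profile` (or plain tibble with start/end/state).
#' @return tibble with `pos` (0-based boundary), `pos_1based` (printed
#'   convention: the 1-based start of the interval beginning at the
#'   transition), `from`, `to`.
#' @export
profile_transitions <- function(profile) {
  n <- nrow(profile)
  if (n < 2) {
    return(tibble(pos = numeric(), pos_1based = numeric(),
                  from = numeric(), to = numeric()))
  }
  tibble(pos = profile$end[-n],
         pos_1based = to_printed(profile$end[-n]),
         from = profile$state[-n], to = profile$state[-1])
}

#' Rearrangement size arithmetic in the printed endpoint convention
#'
#' Reports the triplicated-segment length and duplicated extent of a
#' DUP-TRP/INV-DUP allele the way published endpoint tables do: plain
#' differences of the 1-based transition positions of the anchor-snapped
#' profile (e.g. 103223671 - 103145195 = 78476).
#'
#' @param allele a `cgr_allele` built by [build_dup_trp_inv_dup()].
#' @return tibble with `trp_start`, `trp_size`, `dup_start`, `dup_size`
#'   (printed 1-based positions and sizes).
#' @export
size_arithmetic <- function(allele) {
  prof <- copy_number_profile(allele, snap = TRUE)
  tr <- profile_transitions(prof)
  up2 <- tr[tr$from == 1 & tr$to == 2, ]
  up3 <- tr[tr$from == 2 & tr$to == 3, ]
  dn2 <- tr[tr$from == 3 & tr$to == 2, ]
  dn1 <- tr[tr$from == 2 & tr$to == 1, ]
  if (nrow(up2) != 1 || nrow(up3) != 1 || nrow(dn2) != 1 || nrow(dn1) != 1) {
    abort("profile is not a simple DUP-TRP/INV-DUP pattern")
  }
  tibble(trp_start = up3$pos_1based, trp_size = dn2$pos_1based - up3$pos_1based,
         dup_start = up2$pos_1based, dup_size = dn1$pos_1based - up2$pos_1based)
}

#' Write a profile as BED-graph style TSV
#' @param profile a `cgr_profile`.
#' @param path output path.
#' @return `invisible(profile)`.
#' @export
write_profile <- function(profile, path) {
  out <- tibble(chrom = attr(profile, "chrom") %||% "chr?",
                start = profile$start, end = profile$end,
                copy_number = profile$state)
  readr::write_tsv(out, path)
  invisible(profile)
}

#' Step plot of a copy-number profile
#' @param object a `cgr_profile`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.cgr_profile <- function(object, ...) {
  df <- tidyr::pivot_longer(
    dplyr::mutate(tibble::as_tibble(object), id = dplyr::row_number()),
    cols = c("start", "end"), values_to = "pos")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pos, y = .data$state,
                                   group = .data$id)) +
    ggplot2::geom_line(linewidth = 1, colour = "#b2182b") +
    ggplot2::scale_y_continuous(breaks = 0:8) +
    ggplot2::labs(x = "reference position (bp)", y = "copy number") +
    ggplot2::theme_minimal()
}

# --- sequence emission ------------------------------------------------------

#' Emit the product sequence of an allele
#'
#' Concatenates the segment sequences in order, reverse-complementing
#' inverted segments.
#'
#' @param allele a `cgr_allele`.
#' @param reference character scalar or [Biostrings::DNAString]: the sequence
#'   of the locus extent (its first base is extent start).
#' @return character scalar, the product sequence.
#' @export
emit_sequence <- function(allele, reference) {
  ref <- as.character(reference)
  e0 <- allele$locus$extent[1]
  if (nchar(ref) < allele$locus$extent[2] - e0) {
    abort("reference shorter than the locus extent")
  }
  seg <- allele$segments
  parts <- character(nrow(seg))
  for (i in seq_len(nrow(seg))) {
    s <- substr(ref, seg$start[i] - e0 + 1, seg$end[i] - e0)
    parts[i] <- if (seg$strand[i] == "-") revcomp(s) else s
  }
  paste0(parts, collapse = "")
}

# --- structure reconciliation ----------------------------------------------

#' Enumerate rearrangement structures consistent with observations
#'
#' A finite-grammar matcher over the product structures the package models:
#' reference, tandem duplication, DUP-TRP/INV-DUP (with or without a nested
#' deletion), rolling-circle quadruplication, and the alternative two-step
#' recombination quadruplication (reported for comparison, not scored, since
#' it requires two events in separate generations). Each grammar member is
#' parameterized from the profile's transition points and checked against the
#' observed profile shape and junction multiset; unknown patterns yield no
#' consistent structure rather than a best guess.
#'
#' @param profile a `cgr_profile` (anchor-snapped reporting convention).
#' @param junctions junction multiset tibble as from [junction_multiset()]:
#'   columns `orientation` and `multiplicity` (label optional).
#' @param locus a `cgr_locus`.
#' @return tibble with one row per grammar member: `model`, `consistent`,
#'   `profile_match`, `junction_match`, `params` (list-column), `note`.
#' @export
reconcile_structure <- function(profile, junctions, locus) {
  if (nrow(profile) == 0) abort("empty profile")
  states <- profile$state
  tr <- profile_transitions(profile)
  jn <- junctions
  n_inv <- sum(jn$multiplicity[jn$orientation == "inverted"])
  n_dir <- sum(jn$multiplicity[jn$orientation == "direct"])
  mult <- sort(jn$multiplicity)
  row <- function(model, profile_match, junction_match, params = list(),
                  note = NA_character_, scored = TRUE) {
    tibble(model = model,
           consistent = if (scored) profile_match && junction_match else NA,
           profile_match = profile_match, junction_match = junction_match,
           params = list(params), note = note)
  }
  same <- function(x, y) length(x) == length(y) && all(x == y)
  out <- list()
  out$reference <- row("reference", same(states, 1), nrow(jn) == 0)
  out$tandem <- row(
    "tandem_duplication", same(states, c(1, 2, 1)),
    n_inv == 0 && n_dir == 1 && same(mult, 1),
    params = list(dup_start = tr$pos_1based[tr$to == 2][1],
                  dup_end = tr$pos_1based[tr$to == 1][1]))
  dtid_prof <- same(states, c(1, 2, 3, 2, 1))
  dtid_jn <- n_inv >= 1 && n_dir == 0 && length(mult) <= 2 && all(mult == 1)
  out$dtid <- row(
    "dup_trp_inv_dup", dtid_prof, dtid_jn,
    params = if (dtid_prof) list(
      dup_start = tr$pos_1based[tr$from == 1 & tr$to == 2][1],
      trp_start = tr$pos_1based[tr$from == 2 & tr$to == 3][1],
      trp_end = tr$pos_1based[tr$from == 3 & tr$to == 2][1],
      dup_end = tr$pos_1based[tr$from == 2 & tr$to == 1][1]) else list())
  # nested deletion: DUP-TRP/INV-DUP shape with one CN-1 dip inside the gain
  dtid_del_prof <- length(states) == 7 &&
    (same(states, c(1, 2, 1, 2, 3, 2, 1)) ||
     same(states, c(1, 2, 3, 2, 1, 2, 1)))
  out$dtid_del <- row(
    "dup_trp_inv_dup+nested_deletion", dtid_del_prof,
    n_inv >= 1 && n_dir == 1 && all(mult == 1))
  quad_prof <- same(states, c(1, 2, 4, 3, 1)) ||
    same(states, c(1, 2, 4, 3, 2, 1)) || same(states, c(1, 2, 4, 1))
  quad_jn <- same(mult, c(1, 2))
  out$quad <- row(
    "rolling_circle_quadruplication", quad_prof, quad_jn,
    params = if (quad_prof) list(
      quad_start = tr$pos_1based[tr$to == 4][1],
      quad_end = tr$pos_1based[tr$from == 4][1]) else list())
  out$two_step <- row(
    "two_step_recombination_quadruplication", quad_prof,
    quad_jn, scored = FALSE,
    note = paste("CN-indistinguishable from the rolling-circle model but",
                 "requires two events in separate generations; reported,",
                 "not scored"))
  res <- dplyr::bind_rows(out)
  if (!any(res$consistent, na.rm = TRUE)) {
    res$note[is.na(res$note)] <- "no consistent structure"
  }
  res
}
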