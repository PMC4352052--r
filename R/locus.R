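#' @importFrom rlang .data abort warn `%||%`
#' @importFrom tibble tibble as_tibble
NULL

# Internal coordinates are 0-based half-open throughout; every printed report
# and all file I/O use 1-based inclusive positions so that size arithmetic on
# hg19 endpoints (e.g. 103223671 - 103145195 = 78476) matches published
# conventions. `to_printed()`/`from_printed()` are the only conversion points.

#' Convert between internal 0-based and printed 1-based coordinates
#'
#' Internal coordinates are 0-based half-open; published positions (and all
#' package reports) are 1-based inclusive. `from_printed()` converts a
#' printed position (e.g. an hg19 endpoint from a junction table) to the
#' internal convention; `to_printed()` is its inverse.
#'
#' @param start0 0-based position.
#' @param start1 1-based printed position.
#' @return the converted position.
#' @export
to_printed <- function(start0) start0 + 1L

#' @rdname to_printed
#' @export
from_printed <- function(start1) start1 - 1L

#' Construct a repeat-architecture locus model
#'
#' A `cgr_locus` bundles the reference frame every other function consumes:
#' the chromosome extent, the gene, an ordered set of nested inverted-repeat
#' pairs (outer to inner), canonical copy-number anchor boundaries, and the
#' assay geometry (Southern digest sites and probe, qPCR primer targets).
#'
#' @param chrom chromosome name.
#' @param extent numeric length-2, 0-based half-open extent of the modeled
#'   region.
#' @param repeats tibble with columns `name`, `start`, `end`, `family`,
#'   `approximate` (0-based half-open coordinates).
#' @param pairs tibble with columns `left`, `right`, `family`, `identity`;
#'   rows ordered outer to inner. Members must name rows of `repeats`.
#' @param gene numeric length-2, 0-based half-open gene interval.
#' @param anchors named numeric vector of 0-based boundary positions; must
#'   include `trp_end` and `dup_end`.
#' @param digest list with `sites` (numeric boundary positions) and `probe`
#'   (length-2 interval); may be `NULL`.
#' @param qpcr named list of target interval sets (each a list of length-2
#'   numeric intervals); may be `NULL`.
#' @param scale positive scaling factor the coordinates were built at.
#' @return an object of class `cgr_locus`.
#' @export
new_cgr_locus <- function(chrom, extent, repeats, pairs, gene, anchors,
                          digest = NULL, qpcr = NULL, scale = 1) {
  locus <- structure(
    list(chrom = chrom, extent = as.numeric(extent),
         repeats = as_tibble(repeats), pairs = as_tibble(pairs),
         gene = as.numeric(gene), anchors = anchors,
         digest = digest, qpcr = qpcr, scale = scale),
    class = "cgr_locus")
  validate_locus(locus)
  locus
}

validate_locus <- function(locus) {
  r <- locus$repeats
  if (anyDuplicated(r$name)) {
    abort(paste0("duplicate repeat name: ",
                 paste(unique(r$name[duplicated(r$name)]), collapse = ", ")))
  }
  if (any(r$start >= r$end)) {
    bad <- r$name[r$start >= r$end]
    abort(paste0("empty repeat interval: ", paste(bad, collapse = ", ")))
  }
  for (i in seq_len(nrow(locus$pairs))) {
    p <- locus$pairs[i, ]
    left <- repeat_interval(locus, p$left)
    right <- repeat_interval(locus, p$right)
    if (left[2] > right[1]) {
      abort(paste0("repeat pair ", p$left, "/", p$right,
                   " is mis-ordered: ", p$left, " must lie fully proximal to ",
                   p$right))
    }
    if (p$identity < 0 || p$identity > 1) {
      abort(paste0("identity for pair ", p$left, "/", p$right,
                   " must be in [0, 1]"))
    }
  }
  # nesting: each pair's spacer must contain every more-inner pair
  if (nrow(locus$pairs) > 1) {
    for (i in seq_len(nrow(locus$pairs) - 1)) {
      outer_left <- repeat_interval(locus, locus$pairs$left[i])
      outer_right <- repeat_interval(locus, locus$pairs$right[i])
      for (j in seq(i + 1, nrow(locus$pairs))) {
        inner_left <- repeat_interval(locus, locus$pairs$left[j])
        inner_right <- repeat_interval(locus, locus$pairs$right[j])
        if (inner_left[1] < outer_left[2] || inner_right[2] > outer_right[1]) {
          abort(paste0("nesting violation: pair ", locus$pairs$left[j], "/",
                       locus$pairs$right[j], " is not contained in the spacer of ",
                       locus$pairs$left[i], "/", locus$pairs$right[i]))
        }
      }
    }
  }
  gene_ok <- all(locus$gene[2] <= r$start | locus$gene[1] >= r$end)
  if (!gene_ok) abort("gene interval overlaps a repeat")
  a <- unlist(locus$anchors[c("trp_end", "dup_end")])
  if (any(is.na(a))) abort("anchors 'trp_end' and 'dup_end' are required")
  if (any(a < locus$extent[1] | a > locus$extent[2])) {
    abort("anchor outside locus extent")
  }
  invisible(locus)
}

repeat_interval <- function(locus, name) {
  i <- match(name, locus$repeats$name)
  if (is.na(i)) abort(paste0("unknown repeat: ", name))
  c(locus$repeats$start[i], locus$repeats$end[i])
}

pair_info <- function(locus, pair = NULL) {
  p <- if (is.null(pair)) locus$pairs[match("A", locus$pairs$family), ]
       else locus$pairs[locus$pairs$left == pair | locus$pairs$family == pair, ][1, ]
  if (is.na(p$left)) abort("unknown repeat pair")
  left <- repeat_interval(locus, p$left)
  right <- repeat_interval(locus, p$right)
  list(left_name = p$left, right_name = p$right,
       a1 = left[1], a2 = left[2], b1 = right[1], b2 = right[2],
       len = min(left[2] - left[1], right[2] - right[1]),
       identity = p$identity)
}

# scale-1 canonical coordinates (hg19, 0-based half-open); the triplication
# endpoint 103223671 is the proximal edge of A1a and the duplication endpoint
# 103324335 the proximal edge of A1b, as in the printed size arithmetic.
.plp1_coords <- list(
  chrom = "chrX",
  extent_start = 99000000, extent_end = 103500000,
  gene = c(103031756, 103047547),
  trp_end1 = 103223671, dup_end1 = 103324335,
  repeat_len_A = 20350, repeat_len_CD = 40000, repeat_len_inner = 10000,
  c_start = 103171386,
  a2_start = 103254000, a3_start = 103284000,
  d_gap = 12000,
  probe_off = c(3500, 3000),     # probe upstream of A1a, [a1-3500, a1-3000)
  site_off_prox = 4000,          # BssSI site proximal of the probe
  site_off_h1 = 21000,           # spacer site giving the 25 kb H1 fragment
  site_off_h2 = 25000,           # spacer site giving the 29 kb H2 fragment
  qpcr_black = c(9000, 9150),    # A1a-frame offsets, present in both paralogs
  qpcr_red = c(3000, 2850),      # unique, upstream of A1a
  qpcr_red_black = c(80, 70)     # straddles the A1a proximal edge
)

#' Build the shipped PLP1/Xq22.2 locus fixture
#'
#' The fixture encodes the Xq22.2 inverted-repeat array distal to *PLP1*
#' (hg19): outer C/D repeats (~40 kb, 93% identity), middle A1a/A1b repeats
#' (~20 kb, 99% identity), and inner A2/A3 repeats (~10 kb, 87% identity,
#' boundaries approximate). The canonical distal copy-number anchors are the
#' printed triplication endpoint ChrX:103223671 (= proximal edge of A1a) and
#' duplication endpoint ChrX:103324335 (= proximal edge of A1b). BssSI digest
#' sites are placed symmetrically around A1a/A1b so that the probe fragment is
#' exactly 25 kb on the reference (H1) haplotype and 29 kb on the inverted
#' (H2) haplotype at `scale = 1`; the true hg19 site coordinates are not part
#' of the model, so the sites are engineered to the published band sizes (and
#' flagged as such in the config round-trip).
#'
#' @param scale positive scaling factor applied to all lengths, for desk-scale
#'   work (`scale = 0.1` shrinks the locus tenfold). Positions are scaled as
#'   `round(scale * position)` and interval lengths as `round(scale * length)`
#'   so that scaled lengths are exact.
#' @return a [new_cgr_locus()] object.
#' @examples
#' locus <- plp1_locus()
#' locus$anchors$trp_end + 1  # printed triplication endpoint
#' @export
plp1_locus <- function(scale = 1) {
  stopifnot(scale > 0)
  k <- .plp1_coords
  sp <- function(pos) round(scale * pos)            # scale a position
  sl <- function(len) round(scale * len)            # scale a length
  a1 <- sp(from_printed(k$trp_end1))
  b1 <- sp(from_printed(k$dup_end1))
  la <- sl(k$repeat_len_A)
  lcd <- sl(k$repeat_len_CD)
  li <- sl(k$repeat_len_inner)
  b2 <- b1 + la
  repeats <- tibble(
    name = c("C", "A1a", "A2", "A3", "A1b", "D"),
    start = c(sp(k$c_start), a1, sp(k$a2_start), sp(k$a3_start), b1,
              b2 + sl(k$d_gap)),
    family = c("CD", "A", "inner", "inner", "A", "CD"),
    approximate = c(FALSE, FALSE, TRUE, TRUE, FALSE, FALSE))
  repeats$end <- repeats$start + c(lcd, la, li, li, la, lcd)
  pairs <- tibble(
    left = c("C", "A1a", "A2"), right = c("D", "A1b", "A3"),
    family = c("CD", "A", "inner"),
    identity = c(0.93, 0.99, 0.87), inverted = TRUE)
  anchors <- list(trp_end = a1, dup_end = b1)
  probe <- c(a1 - sl(k$probe_off[1]), a1 - sl(k$probe_off[2]))
  digest <- list(
    enzyme = "BssSI", engineered_to_band_sizes = TRUE,
    sites = c(a1 - sl(k$site_off_prox), a1 + sl(k$site_off_h1),
              b2 - sl(k$site_off_h2), b2 + sl(k$site_off_prox)),
    probe = probe)
  qpcr <- list(
    black = list(c(a1 + sl(k$qpcr_black[1]), a1 + sl(k$qpcr_black[2])),
                 c(b2 - sl(k$qpcr_black[2]), b2 - sl(k$qpcr_black[1]))),
    red = list(c(a1 - sl(k$qpcr_red[1]), a1 - sl(k$qpcr_red[2]))),
    red_black = list(c(a1 - sl(k$qpcr_red_black[1]),
                       a1 + sl(k$qpcr_red_black[2]))))
  new_cgr_locus(
    chrom = k$chrom,
    extent = c(sp(k$extent_start), sp(k$extent_end)),
    repeats = repeats[, c("name", "start", "end", "family", "approximate")],
    pairs = pairs,
    gene = c(sp(k$gene[1]), sp(k$gene[1]) + sl(k$gene[2] - k$gene[1])),
    anchors = anchors, digest = digest, qpcr = qpcr, scale = scale)
}

#' Tidy a locus model into a per-feature tibble
#'
#' @param x a `cgr_locus`.
#' @param ... unused.
#' @return tibble with one row per feature (repeats, gene, probe, anchors),
#'   printed 1-based inclusive coordinates.
#' @export
tidy.cgr_locus <- function(x, ...) {
  feats <- dplyr::bind_rows(
    dplyr::mutate(x$repeats, type = "repeat"),
    tibble(name = "gene", start = x$gene[1], end = x$gene[2],
           family = NA_character_, approximate = FALSE, type = "gene"),
    tibble(name = "southern_probe", start = x$digest$probe[1],
           end = x$digest$probe[2], family = NA_character_,
           approximate = FALSE, type = "anchor"),
    tibble(name = c("trp_end", "dup_end"),
           start = c(x$anchors$trp_end, x$anchors$dup_end),
           end = c(x$anchors$trp_end, x$anchors$dup_end),
           family = NA_character_, approximate = FALSE, type = "anchor"))
  dplyr::mutate(feats, chrom = x$chrom,
                start_1based = to_printed(.data$start),
                end_1based = .data$end,
                .before = 1)
}

#' @export
print.cgr_locus <- function(x, ...) {
  cat("<cgr_locus> ", x$chrom, ":", to_printed(x$extent[1]), "-", x$extent[2],
      " (scale ", x$scale, ")\n", sep = "")
  cat("  repeat pairs (outer to inner):\n")
  for (i in seq_len(nrow(x$pairs))) {
    p <- x$pairs[i, ]
    cat(sprintf("    %s/%s identity %.2f\n", p$left, p$right, p$identity))
  }
  cat("  anchors: trp_end=", to_printed(x$anchors$trp_end),
      " dup_end=", to_printed(x$anchors$dup_end), "\n", sep = "")
  invisible(x)
}

#' Write a locus model as BED + JSON config
#'
#' The BED file (0-based half-open, per the BED standard) carries repeats,
#' the gene and the Southern probe; the JSON config carries pair identities,
#' anchors, digest sites, qPCR targets and the scale. [read_locus()] inverts
#' this exactly (canonical ordering), so write/read round-trips byte-wise.
#'
#' @param locus a `cgr_locus`.
#' @param bed,config output paths.
#' @return `invisible(locus)`.
#' @export
write_locus <- function(locus, bed, config) {
  td <- tidy.cgr_locus(locus)
  td <- td[td$type %in% c("repeat", "gene") | td$name == "southern_probe", ]
  bed_tbl <- tibble(chrom = locus$chrom, start = td$start, end = td$end,
                    name = td$name, score = 0,
                    strand = ifelse(td$name %in% locus$pairs$right, "-", "+"))
  bed_tbl <- bed_tbl[order(bed_tbl$start, bed_tbl$name), ]
  readr::write_tsv(bed_tbl, bed, col_names = FALSE)
  cfg <- list(
    chrom = locus$chrom, scale = locus$scale,
    extent = locus$extent,
    families = stats::setNames(as.list(locus$repeats$family),
                               locus$repeats$name),
    approximate = locus$repeats$name[locus$repeats$approximate],
    pairs = purrr::pmap(locus$pairs, function(left, right, family, identity,
                                              inverted) {
      list(left = left, right = right, family = family,
           identity = identity, inverted = inverted)
    }),
    anchors = list(trp_end = locus$anchors$trp_end,
                   dup_end = locus$anchors$dup_end),
    digest = locus$digest, qpcr = locus$qpcr)
  jsonlite::write_json(cfg, config, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(locus)
}

#' Read a locus model from BED + JSON config
#'
#' Validates all architecture invariants and reports the offending record on
#' failure (mis-ordered pair members, nesting violations, missing anchors).
#'
#' @param bed path to a BED file of repeats/gene/probe annotation.
#' @param config path to the JSON configuration.
#' @return a `cgr_locus`.
#' @export
read_locus <- function(bed, config) {
  cols <- c("chrom", "start", "end", "name", "score", "strand")
  bed_tbl <- readr::read_tsv(bed, col_names = cols,
                             col_types = "cddcdc", progress = FALSE)
  if (any(is.na(bed_tbl$start)) || any(is.na(bed_tbl$end))) {
    abort("malformed BED line: non-numeric start/end")
  }
  cfg <- jsonlite::read_json(config, simplifyVector = FALSE)
  if (is.null(cfg$digest) || !"southern_probe" %in% bed_tbl$name) {
    abort("anchor 'southern_probe' required")
  }
  fam <- unlist(cfg$families)
  rep_tbl <- bed_tbl[bed_tbl$name %in% names(fam), ]
  repeats <- tibble(
    name = rep_tbl$name, start = rep_tbl$start, end = rep_tbl$end,
    family = unname(fam[rep_tbl$name]),
    approximate = rep_tbl$name %in% unlist(cfg$approximate))
  repeats <- repeats[order(match(repeats$name, names(fam))), ]
  pairs <- dplyr::bind_rows(lapply(cfg$pairs, as_tibble))
  gene_row <- bed_tbl[bed_tbl$name == "gene", ]
  if (nrow(gene_row) != 1) abort("exactly one 'gene' BED record required")
  probe_row <- bed_tbl[bed_tbl$name == "southern_probe", ]
  digest <- cfg$digest
  digest$sites <- as.numeric(unlist(digest$sites))
  digest$probe <- c(probe_row$start, probe_row$end)
  qpcr <- lapply(cfg$qpcr, function(t) lapply(t, function(iv) as.numeric(unlist(iv))))
  new_cgr_locus(
    chrom = cfg$chrom, extent = as.numeric(unlist(cfg$extent)),
    repeats = repeats, pairs = pairs,
    gene = c(gene_row$start, gene_row$end),
    anchors = list(trp_end = cfg$anchors$trp_end,
                   dup_end = cfg$anchors$dup_end),
    digest = digest, qpcr = qpcr, scale = cfg$scale %||% 1)
}
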