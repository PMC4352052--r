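# An allele is the single source of truth for a rearranged chromosome: an
# ordered list of oriented reference segments plus the junction list that
# stitches them. Copy-number profiles, assay predictions and emitted
# sequences all derive from this representation.

#' Construct an allele from segments and junctions
#'
#' @param segments tibble with columns `start`, `end` (0-based half-open
#'   reference coordinates) and `strand` (`"+"` direct, `"-"` inverted).
#' @param junctions tibble with columns `label`, `left_pos`, `right_pos`
#'   (0-based boundary positions of the two joined ends), `orientation`
#'   (`"direct"`/`"inverted"`, the orientation of the distal side relative to
#'   the proximal) and `in_repeat` (repeat-pair name or `NA`). One row per
#'   template switch between consecutive segments.
#' @param locus the `cgr_locus` the coordinates refer to.
#' @param provenance free-form list describing the generating event.
#' @return an object of class `cgr_allele`.
#' @export
new_cgr_allele <- function(segments, junctions = empty_junctions(),
                           locus, provenance = list(event = "manual")) {
  segments <- as_tibble(segments)
  junctions <- as_tibble(junctions)
  stopifnot(all(c("start", "end", "strand") %in% names(segments)))
  if (any(segments$end - segments$start < 1)) {
    abort("allele segments must have length >= 1")
  }
  if (nrow(junctions) != max(nrow(segments) - 1, 0)) {
    abort("junction count must equal segment count - 1")
  }
  structure(list(segments = segments, junctions = junctions,
                 locus = locus, provenance = provenance),
            class = "cgr_allele")
}

empty_junctions <- function() {
  tibble(label = character(), left_pos = numeric(), right_pos = numeric(),
         orientation = character(), in_repeat = character())
}

#' The unrearranged reference allele of a locus
#'
#' @param locus a `cgr_locus`.
#' @return a `cgr_allele` with one direct segment spanning the extent.
#' @export
reference_allele <- function(locus) {
  new_cgr_allele(
    tibble(start = locus$extent[1], end = locus$extent[2], strand = "+"),
    locus = locus,
    provenance = list(event = "reference", haplotype = "H1"))
}

#' @export
print.cgr_allele <- function(x, ...) {
  cat("<cgr_allele> ", nrow(x$segments), " segment(s), ",
      nrow(x$junctions), " junction(s); event: ",
      x$provenance$event %||% "?", "\n", sep = "")
  invisible(x)
}

#' Total length of an allele in bp
#' @param allele a `cgr_allele`.
#' @return numeric scalar.
#' @export
allele_length <- function(allele) {
  sum(allele$segments$end - allele$segments$start)
}

#' Tidy an allele into its segment table
#'
#' @param x a `cgr_allele`.
#' @param ... unused.
#' @return tibble of segments with virtual (product) offsets and printed
#'   coordinates.
#' @export
tidy.cgr_allele <- function(x, ...) {
  seg <- x$segments
  len <- seg$end - seg$start
  dplyr::mutate(seg,
                segment = dplyr::row_number(),
                length = len,
                virtual_start = cumsum(dplyr::lag(len, default = 0)),
                virtual_end = cumsum(len),
                start_1based = to_printed(.data$start))
}

#' One-row summary of an allele
#'
#' @param x a `cgr_allele`.
#' @param ... unused.
#' @return tibble with segment/junction counts, total length and maximum
#'   copy number.
#' @export
glance.cgr_allele <- function(x, ...) {
  prof <- copy_number_profile(x, snap = FALSE)
  tibble(n_segments = nrow(x$segments),
         n_junctions = nrow(x$junctions),
         length = allele_length(x),
         max_copy_number = max(prof$state),
         event = x$provenance$event %||% NA_character_)
}

# --- virtual coordinate machinery -----------------------------------------
# The "virtual" frame is the product chromosome: segment lengths laid end to
# end. Boundary semantics: a virtual boundary v in [0, L] falls between
# product bases v-1 and v.

segment_offsets <- function(allele) {
  len <- allele$segments$end - allele$segments$start
  c(0, cumsum(len))
}

# Map a reference boundary position to every virtual boundary it occurs at.
ref_to_virtual <- function(allele, pos) {
  seg <- allele$segments
  off <- segment_offsets(allele)
  out <- numeric(0)
  for (i in seq_len(nrow(seg))) {
    if (pos >= seg$start[i] && pos <= seg$end[i]) {
      v <- if (seg$strand[i] == "+") off[i] + (pos - seg$start[i])
           else off[i] + (seg$end[i] - pos)
      out <- c(out, v)
    }
  }
  sort(unique(out))
}

# Extract the sub-segment list covering virtual interval [vfrom, vto),
# optionally reversing the whole extract (orientation flip).
extract_virtual <- function(allele, vfrom, vto, orientation = "+") {
  stopifnot(vfrom < vto)
  seg <- allele$segments
  off <- segment_offsets(allele)
  if (vfrom < 0 || vto > off[length(off)]) {
    abort("virtual interval outside allele")
  }
  pieces <- list()
  for (i in seq_len(nrow(seg))) {
    s_v <- off[i]; e_v <- off[i + 1]
    lo <- max(s_v, vfrom); hi <- min(e_v, vto)
    if (lo >= hi) next
    if (seg$strand[i] == "+") {
      pieces[[length(pieces) + 1]] <-
        tibble(start = seg$start[i] + (lo - s_v),
               end = seg$start[i] + (hi - s_v), strand = "+")
    } else {
      pieces[[length(pieces) + 1]] <-
        tibble(start = seg$end[i] - (hi - s_v),
               end = seg$end[i] - (lo - s_v), strand = "-")
    }
  }
  out <- dplyr::bind_rows(pieces)
  if (orientation == "-") {
    out <- out[rev(seq_len(nrow(out))), ]
    out$strand <- ifelse(out$strand == "+", "-", "+")
  }
  out
}

# Concatenate segment tables, merging abutting same-strand neighbours so the
# representation stays minimal.
merge_segments <- function(seg) {
  if (nrow(seg) <= 1) return(seg)
  keep <- rep(TRUE, nrow(seg))
  for (i in seq(2, nrow(seg))) {
    j <- max(which(keep[seq_len(i - 1)]))
    same <- seg$strand[j] == seg$strand[i]
    abut <- (seg$strand[i] == "+" && seg$end[j] == seg$start[i]) ||
            (seg$strand[i] == "-" && seg$start[j] == seg$end[i])
    if (same && abut) {
      if (seg$strand[i] == "+") seg$end[j] <- seg$end[i]
      else seg$start[j] <- seg$start[i]
      keep[i] <- FALSE
    }
  }
  seg[keep, ]
}
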