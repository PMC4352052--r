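# Junction characterization from sequence: decompose a junction-spanning
# query into a proximal-flank match, a distal-flank match, and the signature
# of the template switch between them (microhomology, blunt join, or
# templated insertion), tolerating isolated point mismatches which are
# reported as candidate de novo mutations.

# Longest anchored match length between x and y (prefix-to-prefix), allowing
# up to `budget` isolated mismatches: a mismatch is accepted only when
# flanked by >= `flank` exact matches on both sides within the match.
# Returns list(len, exact_len, mismatches).
anchored_match <- function(x, y, budget = 0, flank = 5) {
  n <- min(length(x), length(y))
  eq <- x[seq_len(n)] == y[seq_len(n)]
  exact_len <- if (all(eq)) n else which(!eq)[1] - 1
  len <- exact_len
  mm <- integer()
  i <- exact_len + 1
  while (i <= n && budget > length(mm)) {
    if (i <= flank || i + flank > n) break
    if (!all(eq[(i - flank):(i - 1)]) || !all(eq[(i + 1):(i + flank)])) break
    mm <- c(mm, i)
    j <- i + 1
    while (j <= n && eq[j]) j <- j + 1
    len <- j - 1
    i <- j
  }
  list(len = len, exact_len = exact_len, mismatches = mm)
}

new_junction_call <- function(fields) {
  structure(fields, class = "cgr_junction_call")
}

#' @export
print.cgr_junction_call <- function(x, ...) {
  sig <- if (x$blunt) "blunt" else if (nzchar(x$microhomology)) {
    paste0("microhomology '", x$microhomology, "' (",
           nchar(x$microhomology), " bp)")
  } else paste0("insertion (", nchar(x$insertion), " bp)")
  cat("<junction call> prefix ", x$prefix_match_len, " bp | ", sig,
      " | suffix ", x$suffix_match_len, " bp",
      if (nrow(x$mutations)) paste0(" | ", nrow(x$mutations), " mutation(s)"),
      "\n", sep = "")
  invisible(x)
}

#' Tidy a junction call
#' @param x a `cgr_junction_call`.
#' @param ... unused.
#' @return one-row tibble of the call fields.
#' @export
tidy.cgr_junction_call <- function(x, ...) {
  tibble(prefix_match_len = x$prefix_match_len,
         suffix_match_len = x$suffix_match_len,
         microhomology = x$microhomology,
         microhomology_len = nchar(x$microhomology),
         insertion = x$insertion, blunt = x$blunt,
         distal_orientation = x$distal_orientation,
         n_mutations = nrow(x$mutations))
}

#' Characterize a template switch from sequence
#'
#' Decomposes `query` (a junction-spanning read) against its two flanking
#' templates. The query prefix is matched against the proximal flank
#' (prefix-to-prefix) and the query suffix against the (optionally
#' reverse-complemented) distal flank (suffix-to-suffix). With
#' `overlap = prefix_match_len + suffix_match_len - nchar(query)`:
#' overlap > 0 is microhomology (the overlapping query substring, always an
#' exact match to both templates — mismatches never extend microhomology),
#' overlap == 0 a blunt join, overlap < 0 a templated/untemplated insertion
#' (the unexplained middle). Isolated mismatches within the flank matches
#' (>= 5 exact bases each side, up to `mismatch_budget`) extend the match and
#' are reported as candidate de novo mutations with their offset from the
#' switch point.
#'
#' @param query junction-spanning sequence (>= 20 bp).
#' @param prox_flank proximal template, aligned at its start to the query
#'   start; at least as long as the query.
#' @param dist_flank distal template, aligned at its end to the query end
#'   (after orientation); at least as long as the query.
#' @param dist_orientation `"direct"` or `"inverted"` (distal template is
#'   reverse-complemented before matching).
#' @param mismatch_budget maximum isolated mismatches tolerated per flank.
#' @return a `cgr_junction_call`.
#' @export
call_junction <- function(query, prox_flank, dist_flank,
                          dist_orientation = c("direct", "inverted"),
                          mismatch_budget = 0) {
  dist_orientation <- match.arg(dist_orientation)
  q <- toupper(query); pf <- toupper(prox_flank)
  df <- toupper(if (dist_orientation == "inverted") revcomp(dist_flank)
                else dist_flank)
  n <- nchar(q)
  if (n < 20) abort("query shorter than 20 bp")
  if (nchar(pf) < n || nchar(df) < n) abort("flanks shorter than query")
  qc <- strsplit(q, "")[[1]]
  pc <- strsplit(pf, "")[[1]]
  dc <- strsplit(df, "")[[1]]
  pre <- anchored_match(qc, pc, budget = mismatch_budget)
  suf <- anchored_match(rev(qc), rev(dc), budget = mismatch_budget)
  p <- pre$len; s <- suf$len
  # microhomology must stay an exact overlap: retract mismatch-extended
  # matches until no reported mutation falls inside the overlap region
  repeat {
    ovl <- p + s - n
    bad_pre <- pre$mismatches[pre$mismatches > n - s]
    bad_suf <- suf$mismatches[suf$mismatches > n - p]
    if (ovl <= 0 || (length(bad_pre) == 0 && length(bad_suf) == 0)) break
    if (length(bad_pre)) {
      p <- min(bad_pre) - 1
      pre$mismatches <- pre$mismatches[pre$mismatches < min(bad_pre)]
    }
    if (length(bad_suf)) {
      s <- min(bad_suf) - 1
      suf$mismatches <- suf$mismatches[suf$mismatches < min(bad_suf)]
    }
  }
  if (p >= n || s >= n) {
    abort("query fully explained by one flank: no junction present")
  }
  ovl <- p + s - n
  mh <- if (ovl > 0) substr(q, n - s + 1, p) else ""
  ins <- if (ovl < 0) substr(q, p + 1, n - s) else ""
  muts <- dplyr::bind_rows(
    if (length(pre$mismatches)) tibble(
      side = "proximal", query_pos = pre$mismatches,
      offset = p - pre$mismatches + 1,
      ref = pc[pre$mismatches], alt = qc[pre$mismatches],
      type = "substitution"),
    if (length(suf$mismatches)) tibble(
      side = "distal", query_pos = n - suf$mismatches + 1,
      offset = suf$mismatches - (s - 0) + s - suf$mismatches + 1,
      ref = rev(dc)[suf$mismatches], alt = rev(qc)[suf$mismatches],
      type = "substitution"))
  if (is.null(muts) || nrow(muts) == 0) {
    muts <- tibble(side = character(), query_pos = integer(),
                   offset = integer(), ref = character(), alt = character(),
                   type = character())
  } else {
    # offset = distance from the switch point (end of the relevant match)
    muts$offset <- ifelse(muts$side == "proximal",
                          p - muts$query_pos + 1,
                          muts$query_pos - (n - s))
  }
  new_junction_call(list(
    prefix_match_len = p, suffix_match_len = s,
    microhomology = mh, insertion = ins, blunt = ovl == 0,
    distal_orientation = dist_orientation, mutations = muts,
    query = q))
}

#' Locate the template of a junction insertion
#'
#' Searches both strands of a reference interval for exact or
#' near-exact (`max_mismatch`) placements of an inserted sequence.
#'
#' @param insertion inserted sequence (>= 10 bp).
#' @param search character scalar: the search-space sequence.
#' @param search_offset 0-based reference position of the first base of
#'   `search` (placements are reported in reference coordinates).
#' @param max_mismatch maximum mismatches per placement.
#' @return tibble with `position` (1-based reference), `strand`, `length`,
#'   `mismatches`, sorted by position.
#' @export
locate_insertion_template <- function(insertion, search, search_offset = 0,
                                      max_mismatch = 1) {
  if (nchar(insertion) < 10) abort("insertion shorter than 10 bp")
  if (!nzchar(search)) abort("empty search space")
  subject <- Biostrings::DNAString(toupper(search))
  hits_for <- Biostrings::matchPattern(toupper(insertion), subject,
                                       max.mismatch = max_mismatch)
  hits_rev <- Biostrings::matchPattern(revcomp(insertion), subject,
                                       max.mismatch = max_mismatch)
  mism <- function(hits, pat) {
    vapply(seq_along(hits), function(i) {
      sum(strsplit(as.character(hits[[i]]), "")[[1]] !=
          strsplit(pat, "")[[1]])
    }, numeric(1))
  }
  out <- dplyr::bind_rows(
    if (length(hits_for)) tibble(
      position = Biostrings::start(hits_for) + search_offset,
      strand = "+", length = nchar(insertion),
      mismatches = mism(hits_for, toupper(insertion))),
    if (length(hits_rev)) tibble(
      position = Biostrings::start(hits_rev) + search_offset,
      strand = "-", length = nchar(insertion),
      mismatches = mism(hits_rev, revcomp(insertion))))
  if (is.null(out) || nrow(out) == 0) {
    return(tibble(position = numeric(), strand = character(),
                  length = integer(), mismatches = numeric()))
  }
  dplyr::arrange(out, .data$position)
}

#' Resolve an insertion-bearing junction into its template switches
#'
#' A junction whose middle is a templated insertion implies at least two
#' template switches. This locates the insertion's template(s) and computes
#' the microhomology at each switch by extending the template placement into
#' its own flanking context. When the insertion resolves to templates on
#' opposite strands within `uturn_proximity` bp, the switch is annotated as a
#' "U-turn" (an inverted template switch between close inverted elements).
#'
#' @param call a `cgr_junction_call` with a non-empty insertion.
#' @param search,search_offset search space, as in
#'   [locate_insertion_template()].
#' @param max_mismatch passed through.
#' @param uturn_proximity bp threshold for the U-turn annotation.
#' @return tibble of switches with `template_position`, `template_strand`,
#'   `left_microhomology`, `right_microhomology`, `uturn`.
#' @export
resolve_insertion <- function(call, search, search_offset = 0,
                              max_mismatch = 1, uturn_proximity = 1000) {
  if (!nzchar(call$insertion)) abort("call has no insertion to resolve")
  hits <- locate_insertion_template(call$insertion, search, search_offset,
                                    max_mismatch)
  if (nrow(hits) == 0) return(hits)
  ins <- toupper(call$insertion)
  sch <- toupper(search)
  ext <- purrr::pmap(hits, function(position, strand, length, mismatches) {
    s0 <- position - search_offset  # 1-based in search space
    left_ctx <- substr(sch, max(1, s0 - 50), s0 - 1)
    right_ctx <- substr(sch, s0 + length, min(nchar(sch), s0 + length + 49))
    if (strand == "-") {
      tmp <- revcomp(left_ctx); left_ctx <- revcomp(right_ctx); right_ctx <- tmp
    }
    list(left_ctx = left_ctx, right_ctx = right_ctx)
  })
  q <- call$query
  n <- nchar(q)
  prox_part <- substr(q, 1, call$prefix_match_len)
  dist_part <- substr(q, n - call$suffix_match_len + 1, n)
  tibble(
    template_position = hits$position,
    template_strand = hits$strand,
    left_microhomology = vapply(ext, function(e)
      common_suffix_len(e$left_ctx, prox_part), numeric(1)),
    right_microhomology = vapply(ext, function(e)
      common_prefix_len(e$right_ctx, dist_part), numeric(1)),
    uturn = length(unique(hits$strand)) > 1 &&
      diff(range(hits$position)) <= uturn_proximity)
}

common_prefix_len <- function(x, y) {
  a <- strsplit(x, "")[[1]]; b <- strsplit(y, "")[[1]]
  n <- min(length(a), length(b))
  if (n == 0) return(0)
  d <- which(a[seq_len(n)] != b[seq_len(n)])
  if (length(d)) d[1] - 1 else n
}

common_suffix_len <- function(x, y) {
  common_prefix_len(rev_string(x), rev_string(y))
}

rev_string <- function(x) {
  paste(rev(strsplit(x, "")[[1]]), collapse = "")
}

#' De novo mutations near a junction
#'
#' @param call a `cgr_junction_call` produced with `mismatch_budget >= 1`.
#' @param window report mutations within this many bp of the switch point.
#' @return tibble of mutations (subset of `call$mutations`).
#' @export
flag_denovo_mutations <- function(call, window = 100) {
  call$mutations[call$mutations$offset <= window, ]
}
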