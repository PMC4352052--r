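# Inversion genotyping: discordant fosmid end pairs, Southern band
# quantitation, sex-aware structural-haplotype frequencies, and phasing of
# structural genotypes onto SNP haplotypes.

#' Call inversion support from fosmid end pairs
#'
#' Clones with concordant orientation (`+/-`, insert within the expected
#' range) are uninformative. Clones whose ends map in the same orientation
#' indicate an inversion breakpoint between them; such a clone supports the
#' inversion when it spans one repeat of the mediating pair with both ends in
#' unique sequence (outside every annotated repeat). Per individual:
#' `strong` support means at least one clone independently spanning each
#' repeat, `weak` means one side only, `none` otherwise. Discordant clones
#' spanning neither repeat are tallied as other SVs, not counted as support.
#'
#' @param pairs tibble with columns `start1`, `end1`, `strand1`, `start2`,
#'   `end2`, `strand2`, `clone`, `individual` (BEDPE-like, 0-based,
#'   ends ordered by coordinate).
#' @param locus a `cgr_locus`.
#' @param pair mediating repeat pair (default "A").
#' @param insert_range expected concordant insert range in bp (defaults to
#'   32-48 kb scaled with the locus).
#' @return tibble with `individual`, `spans_left`, `spans_right`, `n_other_sv`,
#'   `call` (`strong`/`weak`/`none`).
#' @export
call_inversion_support <- function(pairs, locus, pair = "A",
                                   insert_range = NULL) {
  p <- pair_info(locus, pair)
  insert_range <- insert_range %||% (c(32000, 48000) * locus$scale)
  reps <- locus$repeats
  in_any_repeat <- function(s, e) {
    purrr::map2_lgl(s, e, function(si, ei) any(si < reps$end & ei > reps$start))
  }
  cl <- dplyr::mutate(pairs,
    insert = .data$end2 - .data$start1,
    concordant = .data$strand1 == "+" & .data$strand2 == "-" &
      .data$insert >= insert_range[1] & .data$insert <= insert_range[2],
    end_in_repeat = in_any_repeat(.data$start1, .data$end1) |
      in_any_repeat(.data$start2, .data$end2),
    spans_left = .data$end1 <= p$a1 & .data$start2 >= p$a2,
    spans_right = .data$end1 <= p$b1 & .data$start2 >= p$b2)
  cl <- dplyr::mutate(cl,
    class = dplyr::case_when(
      concordant ~ "concordant",
      end_in_repeat ~ "excluded_end_in_repeat",
      spans_left ~ "inversion_left",
      spans_right ~ "inversion_right",
      TRUE ~ "other_sv"))
  cl |>
    dplyr::group_by(.data$individual) |>
    dplyr::summarise(
      spans_left = sum(.data$class == "inversion_left"),
      spans_right = sum(.data$class == "inversion_right"),
      n_other_sv = sum(.data$class == "other_sv")) |>
    dplyr::mutate(call = dplyr::case_when(
      .data$spans_left >= 1 & .data$spans_right >= 1 ~ "strong",
      .data$spans_left >= 1 | .data$spans_right >= 1 ~ "weak",
      TRUE ~ "none"))
}

#' Sex-aware structural-haplotype allele frequencies
#'
#' X-linked counting: females contribute two haplotypes, males one. Males
#' recorded as heterozygous are rejected.
#'
#' @param table tibble with `individual`, `sex` (`"M"`/`"F"`), `genotype`
#'   (`"H1"`, `"H2"` or `"H1/H2"`).
#' @return one-row tibble: `n_haplotypes`, `count_H1`, `count_H2`, `freq_H1`,
#'   `freq_H2`.
#' @export
allele_frequencies <- function(table) {
  if (nrow(table) == 0) abort("empty genotype table")
  bad <- table$sex == "M" & table$genotype == "H1/H2"
  if (any(bad)) {
    abort(paste0("male recorded as heterozygous: ",
                 paste(table$individual[bad], collapse = ", ")))
  }
  dose <- ifelse(table$sex == "F", 2L, 1L)
  h2 <- ifelse(table$genotype == "H2", dose,
               ifelse(table$genotype == "H1/H2", 1L, 0L))
  n <- sum(dose)
  tibble(n_haplotypes = n, count_H1 = n - sum(h2), count_H2 = sum(h2),
         freq_H1 = (n - sum(h2)) / n, freq_H2 = sum(h2) / n)
}

#' Genotype from quantitated Southern band intensities
#'
#' One band means hemi-/homozygosity for that band's haplotype; two bands
#' give the larger:smaller intensity ratio, called heterozygous when near 1.
#' Ratios outside the balanced window are the patient dosage signal and are
#' classified with [classify_progenitor()].
#'
#' @param bands tibble with `size` (bp) and `volume` (raw intensity).
#' @param h1_size,h2_size expected fragment sizes of the two haplotypes
#'   (defaults 25/29 kb at scale 1, scaled via `scale`).
#' @param scale locus scale the band sizes refer to.
#' @param size_tol relative tolerance for matching a band to a class.
#' @return one-row tibble: `call`, `ratio`, `n_bands`.
#' @export
quantitate_genotype <- function(bands, h1_size = 25000, h2_size = 29000,
                                scale = 1, size_tol = 0.05) {
  if (nrow(bands) > 2) abort("more than two bands: not a two-allele assay")
  if (nrow(bands) == 0) abort("no bands")
  h1 <- h1_size * scale; h2 <- h2_size * scale
  classify_band <- function(size) {
    if (abs(size - h1) / h1 <= size_tol) "H1"
    else if (abs(size - h2) / h2 <= size_tol) "H2"
    else abort(paste0("band of ", size, " bp matches neither expected class"))
  }
  if (nrow(bands) == 1) {
    return(tibble(call = classify_band(bands$size), ratio = NA_real_,
                  n_bands = 1L))
  }
  cls <- vapply(bands$size, classify_band, character(1))
  if (length(unique(cls)) != 2) abort("two bands of the same size class")
  ratio <- bands$volume[cls == "H2"] / bands$volume[cls == "H1"]
  call <- if (classify_progenitor(ratio) == "balanced") "H1/H2"
          else classify_progenitor(ratio)
  tibble(call = call, ratio = ratio, n_bands = 2L)
}

#' Phase structural genotypes onto SNP haplotypes
#'
#' Groups phased SNP haplotype strings over the inter-repeat interval by
#' exact match, assigns each informative structural allele (hemizygous males
#' and homozygous females only; heterozygotes cannot be phased) to its
#' group, and reports whether the inversion is recurrent (H2 alleles on more
#' than one SNP haplotype group).
#'
#' @param snp_haplotypes tibble with `individual`, `haplotype` (1 or 2; males
#'   have one row) and `alleles` (phased allele string over the SNP columns).
#' @param sv_calls genotype tibble as in [allele_frequencies()].
#' @return list with `assignments` (tibble: individual, group, sv), `summary`
#'   (tibble: group, n_H1, n_H2), `recurrent`, `note`.
#' @export
phase_sv_on_snps <- function(snp_haplotypes, sv_calls) {
  informative <- sv_calls[sv_calls$genotype %in% c("H1", "H2"), ]
  if (nrow(informative) == 0) {
    return(list(assignments = tibble(), summary = tibble(),
                recurrent = NA, note = "no informative individuals"))
  }
  missing <- setdiff(informative$individual, snp_haplotypes$individual)
  if (length(missing)) {
    abort(paste0("individual(s) in the SV table absent from the SNP matrix: ",
                 paste(missing, collapse = ", ")))
  }
  groups <- tibble(alleles = unique(snp_haplotypes$alleles)) |>
    dplyr::mutate(group = paste0("g", dplyr::row_number()))
  asn <- snp_haplotypes |>
    dplyr::inner_join(informative, by = "individual") |>
    dplyr::left_join(groups, by = "alleles") |>
    dplyr::transmute(.data$individual, .data$group, sv = .data$genotype)
  summary <- asn |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(n_H1 = sum(.data$sv == "H1"),
                     n_H2 = sum(.data$sv == "H2"))
  recurrent <- sum(summary$n_H2 > 0) >= 2
  list(assignments = asn, summary = summary, recurrent = recurrent,
       note = if (recurrent) {
         paste0("H2 alleles on ", sum(summary$n_H2 > 0),
                " distinct SNP haplotype groups (split ",
                paste(sort(summary$n_H2[summary$n_H2 > 0], decreasing = TRUE),
                      collapse = "/"), " of ", sum(summary$n_H2),
                "): recurrent")
       } else "all H2 alleles on one SNP haplotype group")
}
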