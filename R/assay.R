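# In-silico predictions of the orthogonal assays: Southern restriction
# dosage, qPCR/dPCR copy counts, junction multiplicities, marker zygosity.
# All predictions walk the allele's segment list at coordinate scale; no
# sequence is required (sites and primer targets are reference intervals
# mapped through the product).

as_genotype <- function(x) {
  if (inherits(x, "cgr_allele")) list(x)
  else if (is.list(x) && all(vapply(x, inherits, logical(1), "cgr_allele"))) x
  else abort("expected a cgr_allele or list of cgr_allele")
}

# virtual boundary positions of every occurrence of a reference boundary
# across an allele's product chromosome (interior occurrences only)
virtual_occurrences <- function(allele, pos) {
  seg <- allele$segments
  off <- segment_offsets(allele)
  out <- numeric(0)
  for (i in seq_len(nrow(seg))) {
    if (pos > seg$start[i] && pos < seg$end[i]) {
      v <- if (seg$strand[i] == "+") off[i] + (pos - seg$start[i])
           else off[i] + (seg$end[i] - pos)
      out <- c(out, v)
    }
  }
  sort(out)
}

# virtual intervals of every segment copy fully containing [iv1, iv2)
virtual_containments <- function(allele, iv) {
  seg <- allele$segments
  off <- segment_offsets(allele)
  out <- list()
  for (i in seq_len(nrow(seg))) {
    if (iv[1] >= seg$start[i] && iv[2] <= seg$end[i]) {
      v <- if (seg$strand[i] == "+") {
        c(off[i] + (iv[1] - seg$start[i]), off[i] + (iv[2] - seg$start[i]))
      } else {
        c(off[i] + (seg$end[i] - iv[2]), off[i] + (seg$end[i] - iv[1]))
      }
      out[[length(out) + 1]] <- v
    }
  }
  out
}

#' Predict the Southern band profile of a genotype
#'
#' In-silico digestion: restriction-site boundaries are mapped through every
#' allele's segment list into product coordinates, each probe copy is located,
#' and the probe-containing fragment sizes are counted. Fragments within
#' `size_tol` (relative) are pooled into one band class.
#'
#' @param genotype a `cgr_allele` or list of alleles (one per chromosome:
#'   one for a male, two for a female).
#' @param digest digest model (defaults to the locus digest): list with
#'   `sites` (boundary positions) and `probe` (interval).
#' @param size_tol relative size tolerance for pooling fragments into a band
#'   class (gel resolution, default 5%).
#' @return a `cgr_bands` tibble with `size` (bp, class representative) and
#'   `count` (number of probe-containing fragments of that class).
#' @export
southern_profile <- function(genotype, digest = NULL, size_tol = 0.05) {
  alleles <- as_genotype(genotype)
  digest <- digest %||% alleles[[1]]$locus$digest
  if (is.null(digest)) abort("no digest model available")
  sizes <- numeric(0)
  for (al in alleles) {
    vsites <- sort(unlist(lapply(digest$sites, function(s)
      virtual_occurrences(al, s))))
    probes <- virtual_containments(al, digest$probe)
    if (length(probes) == 0) next
    for (pv in probes) {
      lo <- vsites[vsites <= pv[1]]
      hi <- vsites[vsites >= pv[2]]
      if (length(lo) == 0 || length(hi) == 0) {
        abort("probe copy with no flanking restriction site: unbounded fragment")
      }
      sizes <- c(sizes, min(hi) - max(lo))
    }
  }
  if (length(sizes) == 0) {
    out <- tibble(size = numeric(), count = integer())
  } else {
    sizes <- sort(sizes)
    cls <- cumsum(c(1, diff(sizes) / sizes[-length(sizes)] > size_tol))
    out <- tibble(size = sizes, cls = cls) |>
      dplyr::group_by(.data$cls) |>
      dplyr::summarise(size = stats::median(.data$size),
                       count = dplyr::n()) |>
      dplyr::select("size", "count")
  }
  structure(out, class = c("cgr_bands", class(out)))
}

#' Bar plot of a Southern band profile
#' @param object a `cgr_bands` tibble.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.cgr_bands <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = factor(.data$size), y = .data$count)) +
    ggplot2::geom_col(fill = "#2166ac", width = 0.5) +
    ggplot2::labs(x = "fragment size (bp)", y = "probe-fragment dosage") +
    ggplot2::theme_minimal()
}

#' Dosage ratio of the larger to the smaller band class
#'
#' @param bands a `cgr_bands` tibble with exactly two classes.
#' @return numeric: count(larger fragment) / count(smaller fragment).
#' @export
band_dosage_ratio <- function(bands) {
  if (nrow(bands) != 2) abort("expected exactly two band classes")
  bands$count[which.max(bands$size)] / bands$count[which.min(bands$size)]
}

#' Classify the progenitor haplotype from a band dosage ratio
#'
#' The ratio of inverted-haplotype-sized to reference-sized probe fragments:
#' ~2 indicates the rearrangement arose on the inverted haplotype (H2), ~0.5
#' on the reference haplotype (H1), ~1 is balanced (unaffected heterozygote).
#'
#' @param ratio_29_to_25 positive band dosage ratio (29 kb class : 25 kb
#'   class).
#' @param h2_threshold,h1_threshold decision thresholds.
#' @return `"H2_origin"`, `"H1_origin"` or `"balanced"`.
#' @export
classify_progenitor <- function(ratio_29_to_25, h2_threshold = 1.5,
                                h1_threshold = 0.75) {
  if (!is.finite(ratio_29_to_25) || ratio_29_to_25 <= 0) {
    abort("band ratio must be positive")
  }
  if (ratio_29_to_25 >= h2_threshold) "H2_origin"
  else if (ratio_29_to_25 <= h1_threshold) "H1_origin"
  else "balanced"
}

#' Predict qPCR copy number for primer-pair targets
#'
#' A primer pair amplifies once per contiguous occurrence of its target
#' interval in the genotype's alleles, in either orientation. Targets with
#' several reference placements (e.g. a pair internal to both repeat
#' paralogs) count every placement.
#'
#' @param genotype a `cgr_allele` or list of alleles.
#' @param pairs character vector of target names defined in the locus qPCR
#'   model (default: all of them).
#' @param control_copies copy number of the autosomal control target
#'   (default 2).
#' @return tibble with `pair`, `copies`, `ratio_to_control`.
#' @export
qpcr_copy_number <- function(genotype, pairs = NULL, control_copies = 2) {
  alleles <- as_genotype(genotype)
  qp <- alleles[[1]]$locus$qpcr
  if (is.null(qp)) abort("no qPCR targets defined on the locus")
  pairs <- pairs %||% names(qp)
  bad <- setdiff(pairs, names(qp))
  if (length(bad)) abort(paste0("unknown primer pair: ",
                                paste(bad, collapse = ", ")))
  copies <- vapply(unname(pairs), function(p) {
    sum(vapply(alleles, function(al) {
      sum(vapply(qp[[p]], function(iv)
        length(virtual_containments(al, iv)), numeric(1)))
    }, numeric(1)))
  }, numeric(1), USE.NAMES = FALSE)
  tibble(pair = pairs, copies = copies,
         ratio_to_control = copies / control_copies)
}

#' Digital PCR copies per genome
#'
#' Normalizes a junction assay concentration by the autosomal reference
#' (RNase P, two copies per genome):
#' `copies/genome = jct_conc / (rnasep_conc / 2)`.
#'
#' @param jct_conc junction assay concentration (copies/uL).
#' @param rnasep_conc RNase P reference concentration (copies/uL).
#' @return numeric copies per genome.
#' @export
dpcr_copies_per_genome <- function(jct_conc, rnasep_conc) {
  if (any(rnasep_conc <= 0)) abort("reference concentration must be positive")
  jct_conc / (rnasep_conc / 2)
}

#' Multiplicity of a junction label in an allele
#'
#' @param allele a `cgr_allele`.
#' @param label junction label (e.g. `"FoSTeS2/3"`).
#' @return integer count of that label in the unrolled segment list.
#' @export
junction_multiplicity <- function(allele, label) {
  labs <- allele$junctions$label
  if (!label %in% labs) {
    abort(paste0("unknown junction label '", label, "'; present: ",
                 paste(unique(labs), collapse = ", ")))
  }
  sum(labs == label)
}

#' Predict marker zygosity for intra- vs inter-chromosomal origin
#'
#' For a hemizygous male proband carrying extra copies of
#' `duplicated_interval`: an intra-chromosomal event copies the proband's
#' single haplotype, so every marker in the duplicated region stays
#' monomorphic; an inter-chromosomal event (between the two maternal
#' homologs) renders every maternally heterozygous marker biallelic.
#'
#' @param markers tibble with `marker`, `pos` (0-based), `hap1`, `hap2` (the
#'   two maternal alleles).
#' @param event `"intra"` or `"inter"`.
#' @param duplicated_interval length-2 numeric interval.
#' @return tibble with `marker`, `zygosity` (`"monomorphic"`/`"biallelic"`),
#'   `informative` (maternal heterozygosity).
#' @export
marker_zygosity <- function(markers, event = c("intra", "inter"),
                            duplicated_interval) {
  event <- match.arg(event)
  if (any(markers$pos < duplicated_interval[1] |
          markers$pos >= duplicated_interval[2])) {
    bad <- markers$marker[markers$pos < duplicated_interval[1] |
                            markers$pos >= duplicated_interval[2]]
    abort(paste0("marker outside modeled interval: ",
                 paste(bad, collapse = ", ")))
  }
  informative <- markers$hap1 != markers$hap2
  zyg <- if (event == "intra") rep("monomorphic", nrow(markers))
         else ifelse(informative, "biallelic", "monomorphic")
  tibble(marker = markers$marker, zygosity = zyg, informative = informative)
}
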