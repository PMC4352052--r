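# Junction-record tables: the published endpoint/junction table dialect.
# One row per patient junction (Jct2): proximal endpoints, sizes, and the
# junction descriptor columns. Microhomology is encoded by capital letters
# inside a lowercase junction-context string; "..." separates the strings of
# multi-switch junctions; small untemplated insertions appear in brackets and
# larger templated insertions as "<n>bp of <position>(<strand>)".

#' Read a junction-record table
#'
#' Parses the TSV dialect of published DUP-TRP/INV-DUP junction tables and
#' derives per-row signature columns. `N/A` means the column does not apply.
#'
#' @param path TSV path; defaults to the table of 16 Xq22.2 junctions
#'   shipped with the package.
#' @return tibble of junction records with derived columns
#'   `microhomology_runs` (list of capital-run lengths), `has_microhomology`,
#'   `is_blunt`, `has_template_insertion`, `has_chimeric_element`.
#' @export
read_junction_table <- function(path = NULL) {
  path <- path %||% system.file("extdata", "xq22_jct2_table.tsv",
                                package = "xq22cgr", mustWork = TRUE)
  rec <- readr::read_tsv(path, col_types = readr::cols(
    patient = "c", array = "c", trp_start = "d", trp_size = "d",
    dup_start = "d", dup_size = "d", microhomology = "c", insertion = "c",
    blunt = "c", chimeric_elements = "c", repeat_elements = "c",
    denovo_mutations = "i", flags = "c"), progress = FALSE)
  need <- c("patient", "trp_start", "microhomology", "insertion", "blunt")
  miss <- setdiff(need, names(rec))
  if (length(miss)) {
    abort(paste0("junction table missing column(s): ",
                 paste(miss, collapse = ", ")))
  }
  na_col <- function(x) is.na(x) | x == "N/A"
  runs <- lapply(rec$microhomology, microhomology_runs)
  bad <- which(!na_col(rec$microhomology) &
                 vapply(runs, length, integer(1)) == 0)
  if (length(bad)) {
    abort(paste0("unparseable microhomology descriptor in row(s): ",
                 paste(rec$patient[bad], collapse = ", ")))
  }
  dplyr::mutate(rec,
    microhomology_runs = runs,
    has_microhomology = !na_col(.data$microhomology),
    is_blunt = !na_col(.data$blunt),
    has_template_insertion = !na_col(.data$insertion) &
      grepl("bp of", .data$insertion, fixed = TRUE),
    has_chimeric_element = !na_col(.data$chimeric_elements))
}

# capital-letter run lengths within a junction descriptor string; runs are
# found within letter tokens so that runs on either side of a "..." separator
# are not merged
microhomology_runs <- function(x) {
  if (is.na(x) || x == "N/A") return(integer())
  tokens <- strsplit(x, "[^A-Za-z]+")[[1]]
  out <- unlist(lapply(tokens, function(tk) {
    m <- gregexpr("[A-Z]+", tk)[[1]]
    if (m[1] == -1) integer() else attr(m, "match.length")
  }))
  as.integer(out)
}

#' Summarize a junction-record table
#'
#' Deterministic cohort-level counts: junction signature classes, the
#' microhomology length histogram, and the de novo mutation rate per
#' sequenced bp (mutations / (junctions x mean sequenced bp per junction)).
#'
#' @param records tibble from [read_junction_table()].
#' @param mean_sequenced_bp mean bp sequenced per junction (default 600).
#' @return list with `counts` (one-row tibble) and `microhomology_histogram`.
#' @export
summarize_junction_table <- function(records, mean_sequenced_bp = 600) {
  if (nrow(records) == 0) {
    return(list(
      counts = tibble(n_records = 0L, n_microhomology = 0L, n_blunt = 0L,
                      n_template_insertion = 0L, n_chimeric = 0L,
                      n_denovo_mutations = 0L, mutation_rate_per_bp = 0),
      microhomology_histogram = tibble(length = integer(), n = integer())))
  }
  mut <- sum(records$denovo_mutations %||% 0, na.rm = TRUE)
  counts <- tibble(
    n_records = nrow(records),
    n_microhomology = sum(records$has_microhomology),
    n_blunt = sum(records$is_blunt),
    n_template_insertion = sum(records$has_template_insertion),
    n_chimeric = sum(records$has_chimeric_element),
    n_denovo_mutations = mut,
    mutation_rate_per_bp = mut / (nrow(records) * mean_sequenced_bp))
  hist <- tibble(length = unlist(records$microhomology_runs)) |>
    dplyr::count(.data$length)
  list(counts = counts, microhomology_histogram = hist)
}
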