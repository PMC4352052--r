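#' Tidy generic
#'
#' Turn a model object into a tibble of its per-element results
#' (broom-style).
#' @param x object.
#' @param ... passed to methods.
#' @export
tidy <- function(x, ...) UseMethod("tidy")

#' Glance generic
#'
#' One-row tibble summary of a model object (broom-style).
#' @param x object.
#' @param ... passed to methods.
#' @export
glance <- function(x, ...) UseMethod("glance")

#' Reverse complement of a DNA string
#' @param x character scalar.
#' @return character scalar.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

#' Read/write FASTA
#'
#' Thin wrappers over Biostrings for the package's character-vector
#' sequence convention.
#' @param path file path.
#' @return `read_fasta()`: named character vector.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(x), names(x))
}

#' @rdname read_fasta
#' @param seqs named character vector of sequences.
#' @export
write_fasta <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(unlist(seqs))
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

# run code with a temporarily-seeded RNG, restoring global state afterwards
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

random_dna <- function(n) {
  paste0(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# per-base substitution at the given rate; substitutions only (paralog
# divergence model), returns list(seq, positions)
mutate_dna <- function(x, rate) {
  if (rate <= 0) return(list(seq = x, positions = integer()))
  chars <- strsplit(x, "", fixed = TRUE)[[1]]
  hit <- which(stats::runif(length(chars)) < rate)
  for (i in hit) {
    chars[i] <- sample(setdiff(c("A", "C", "G", "T"), toupper(chars[i])), 1)
  }
  list(seq = paste0(chars, collapse = ""), positions = hit)
}
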