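# Accessors for the small plain-text fixtures shipped with the package.
# Files suffixed "_synthetic" are constructed from published summary
# descriptions (counts and geometries), not from deposited data.

fixture_path <- function(name) {
  system.file("extdata", name, package = "xq22cgr", mustWork = TRUE)
}

#' Shipped fixtures
#'
#' * `read_fosmid_fixture()`: a synthetic fosmid end-pair table emulating the
#'   human genome structural variation resource at this locus: 9 individuals,
#'   of whom 5 carry clones spanning both repeats in inversion orientation
#'   (strong support), 3 span one repeat (weak), and 1 is concordant-only.
#' * `read_genotype_fixture()`: the 17-individual Southern inversion
#'   genotype table (3 homozygous-H2 females, 1 hemizygous-H2 male, 5
#'   homozygous-H1 females, 2 hemizygous-H1 males, 6 heterozygous females).
#' * `read_phasing_fixture()`: phased SNP haplotype strings for the
#'   informative individuals of the genotype table, encoding the 6/7 vs 1/7
#'   distribution of inversion alleles over the two SNP haplotype groups.
#'
#' @return a tibble (see details above).
#' @export
read_fosmid_fixture <- function() {
  readr::read_tsv(fixture_path("hgsv_fosmid_support_synthetic.tsv"),
                  col_types = "cddcddccc", progress = FALSE)
}

#' @rdname read_fosmid_fixture
#' @export
read_genotype_fixture <- function() {
  readr::read_tsv(fixture_path("southern_inversion_genotypes.tsv"),
                  col_types = "cccc", progress = FALSE)
}

#' @rdname read_fosmid_fixture
#' @export
read_phasing_fixture <- function() {
  readr::read_tsv(fixture_path("snp_sv_phasing_synthetic.tsv"),
                  col_types = "cic", progress = FALSE)
}
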