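# Independent oracles and tiny fixtures used across the suite. The oracles
# deliberately use the dumbest correct algorithm (per-base counting, full
# split enumeration) so they share no code path with the implementation.

# brute-force per-base coverage of a toy allele over its locus extent
coverage_oracle <- function(allele) {
  ext <- allele$locus$extent
  cov <- integer(ext[2] - ext[1])
  for (i in seq_len(nrow(allele$segments))) {
    s <- allele$segments$start[i] - ext[1]
    e <- allele$segments$end[i] - ext[1]
    cov[(s + 1):e] <- cov[(s + 1):e] + 1L
  }
  r <- rle(cov)
  ends <- cumsum(r$lengths)
  tibble::tibble(start = ext[1] + c(0, ends[-length(ends)]),
                 end = ext[1] + ends, state = as.numeric(r$values))
}

# exhaustive split-point junction oracle: maximal exact anchored prefix and
# suffix by direct per-position comparison, then the same classification
# arithmetic applied by definition
junction_oracle <- function(query, prox, dist) {
  q <- strsplit(toupper(query), "")[[1]]
  p <- strsplit(toupper(prox), "")[[1]]
  d <- strsplit(toupper(dist), "")[[1]]
  n <- length(q)
  pre <- 0
  for (t in seq_len(n)) {
    if (all(q[1:t] == p[1:t])) pre <- t else break
  }
  suf <- 0
  nd <- length(d)
  for (t in seq_len(n)) {
    if (all(q[(n - t + 1):n] == d[(nd - t + 1):nd])) suf <- t else break
  }
  ovl <- pre + suf - n
  list(prefix = pre, suffix = suf, overlap = ovl,
       microhomology = if (ovl > 0) substr(toupper(query), n - suf + 1, pre) else "",
       insertion = if (ovl < 0) substr(toupper(query), pre + 1, n - suf) else "",
       blunt = ovl == 0)
}

# small locus for coordinate-level toy tests (digest/qPCR geometry mirrors
# the main fixture at 1/100 the size)
toy_locus <- function() {
  a1 <- 1000; la <- 200; b1 <- 1800
  b2 <- b1 + la
  new_cgr_locus(
    chrom = "toy", extent = c(0, 3000),
    repeats = tibble::tibble(
      name = c("A1a", "A1b"), start = c(a1, b1), end = c(a1 + la, b2),
      family = "A", approximate = FALSE),
    pairs = tibble::tibble(left = "A1a", right = "A1b", family = "A",
                           identity = 0.99, inverted = TRUE),
    gene = c(100, 300),
    anchors = list(trp_end = a1, dup_end = b1),
    digest = list(sites = c(a1 - 40, a1 + 210, b2 - 250, b2 + 40),
                  probe = c(a1 - 35, a1 - 30)),
    qpcr = list(black = list(c(a1 + 90, a1 + 95), c(b2 - 95, b2 - 90)),
                red = list(c(a1 - 30, a1 - 25)),
                red_black = list(c(a1 - 2, a1 + 2))),
    scale = 0.01)
}

# random composed event allele on the toy locus (for oracle equivalence)
random_toy_allele <- function() {
  locus <- toy_locus()
  type <- sample(c("reference", "inversion", "tandem_duplication",
                   "dup_trp_inv_dup", "quadruplication"), 1)
  ev <- switch(type,
    reference = list(type = "reference"),
    inversion = list(type = "inversion",
                     crossover = sample(50:150, 1)),
    tandem_duplication = {
      s <- sample(200:800, 1)
      list(type = "tandem_duplication", dup_start = s,
           dup_end = s + sample(100:1000, 1))
    },
    dup_trp_inv_dup = list(
      type = "dup_trp_inv_dup",
      trp_start = sample(500:900, 1), dup_start = sample(100:450, 1),
      jct1_crossover = sample(20:180, 1),
      progenitor = sample(c("H1", "H2"), 1)),
    quadruplication = {
      c1 <- sample(300:500, 1)
      clen <- sample(100:300, 1)
      list(type = "quadruplication", circle = c(c1, c1 + clen),
           rolled_length = sample(clen:(3 * clen), 1),
           termination_crossover = sample(50:(c1 - 10), 1))
    })
  build_event_allele_pub(locus, ev)
}

# exported-surface wrapper (build_event_allele is internal)
build_event_allele_pub <- function(locus, ev) {
  getFromNamespace("build_event_allele", "xq22cgr")(locus, ev)
}

# plant a junction query with an exact overlap of `ovl` (>=0) or an
# insertion of `-ovl` bases (ovl < 0); flanks are mismatched just beyond
# their matched parts so the planted decomposition is maximal
plant_junction <- function(n = 40, prefix = NULL, ovl = 0) {
  repeat {
    q <- random_dna_str(n)
    prefix <- prefix %||% sample(ceiling(n / 3):floor(2 * n / 3), 1)
    suffix <- n - prefix + ovl
    if (ovl < 0) suffix <- n - prefix + ovl  # leaves -ovl unexplained bases
    if (suffix < 1 || suffix > n - 1) { prefix <- NULL; next }
    prox <- paste0(substr(q, 1, prefix), flip_base(substr(q, prefix + 1, prefix + 1)),
                   random_dna_str(n))
    dist_core <- substr(q, n - suffix + 1, n)
    dist <- paste0(random_dna_str(n),
                   flip_base(substr(q, n - suffix, n - suffix)), dist_core)
    or <- junction_oracle(q, prox, dist)
    if (or$overlap == ovl && or$prefix == prefix && or$suffix == suffix) {
      return(list(query = q, prox = prox, dist = dist,
                  prefix = prefix, suffix = suffix, ovl = ovl))
    }
    prefix <- NULL
  }
}

random_dna_str <- function(n) {
  paste0(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

flip_base <- function(b) {
  if (b == "") return("A")
  sample(setdiff(c("A", "C", "G", "T"), toupper(b)), 1)
}

`%||%` <- rlang::`%||%`

mutate_dna_pub <- function(x, rate) {
  getFromNamespace("mutate_dna", "xq22cgr")(x, rate)
}
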