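# builds a paralog pair in a shared frame with PSVs planted at the given
# positions, plus a chimera switching from A to B after position `switch_at`
make_paralogs <- function(frame_len, psv_pos, switch_at = NULL) {
  a <- random_dna_str(frame_len)
  ac <- strsplit(a, "")[[1]]
  bc <- ac
  for (p in psv_pos) bc[p] <- setdiff(c("A", "C", "G", "T"), ac[p])[1]
  b <- paste0(bc, collapse = "")
  chim <- if (!is.null(switch_at)) {
    paste0(substr(a, 1, switch_at), substr(b, switch_at + 1, frame_len))
  }
  list(a = a, b = b, chimera = chim)
}

test_that("PSV calling recovers planted divergence exactly", {
  set.seed(5)
  pp <- make_paralogs(2000, c(50, 300, 777, 1500, 1999))
  pm <- call_psvs(pp$a, pp$b)
  expect_equal(pm$pos, c(50, 300, 777, 1500, 1999))
  expect_true(all(pm$a != pm$b))
  # symmetry: swapping paralogs swaps the base columns only
  pm_swap <- call_psvs(pp$b, pp$a)
  expect_equal(pm_swap$pos, pm$pos)
  expect_equal(pm_swap$a, pm$b)
  expect_equal(pm_swap$b, pm$a)
  # identical sequences: empty map
  expect_equal(nrow(call_psvs(pp$a, pp$a)), 0)
  expect_error(call_psvs("ACGT", "ACGT"), ">= 100 bp")
})

test_that("PSV count of simulated 99%-identity paralogs is binomial", {
  set.seed(12)
  n <- 20000
  pair <- mutate_dna_pub(random_dna_str(n), 0.01)
  # expectation 200, sd ~14: realized count within 3 sigma
  expect_lt(abs(length(pair$positions) - 200), 3 * sqrt(200 * 0.99))
})

test_that("alignment path handles length-variant paralogs", {
  set.seed(6)
  pp <- make_paralogs(300, c(40, 220))
  # delete 5 bp from b: PSVs still called, indel recorded separately
  b_del <- paste0(substr(pp$b, 1, 99), substr(pp$b, 105, 300))
  pm <- call_psvs(pp$a, b_del)
  expect_setequal(pm$pos, c(40, 220))
  indels <- attr(pm, "indels")
  expect_equal(nrow(indels), 1)
  expect_equal(indels$length, 5)
  # unalignable pair is rejected
  expect_error(call_psvs(random_dna_str(200), random_dna_str(201)),
               "unalignable")
})

test_that("crossover mapping reproduces the chimeric-clone fixture geometry", {
  # 7 A-specific PSVs in the 1 kb before a 334 bp identity block and 10
  # B-specific PSVs in the 200 bp after it, switch inside the block
  set.seed(42)
  frame <- 22000
  before <- sort(sample(18000:18990, 6))
  last_a <- 19000
  first_b <- last_a + 335            # identity block of 334 bp between them
  after <- sort(c(first_b, sample((first_b + 1):(first_b + 199), 9)))
  psv_pos <- c(before, last_a, after)
  pp <- make_paralogs(frame, psv_pos, switch_at = last_a + 100)
  pm <- call_psvs(pp$a, pp$b)
  expect_equal(nrow(pm), 17)
  cx <- map_crossover(pp$chimera, pp$a, pp$b, psvs = pm)
  expect_equal(cx$identity_block_len, 334)
  expect_equal(cx$direction, "A->B")
  expect_false(cx$unresolvable)
  # repeat-internal breakpoint with 24 bp of microhomology between PSVs
  pp2 <- make_paralogs(1000, c(400, 425), switch_at = 410)
  cx2 <- map_crossover(pp2$chimera, pp2$a, pp2$b)
  expect_equal(cx2$identity_block_len, 24)
})

test_that("non-chimeric and degenerate inputs are diagnosed", {
  pp <- make_paralogs(500, c(100, 400), switch_at = 250)
  expect_error(map_crossover(pp$a, pp$a, pp$b), "not chimeric")
  expect_error(map_crossover(pp$b, pp$a, pp$b), "not chimeric")
  expect_error(map_crossover(pp$a, pp$a, pp$a), "no PSVs")
})

test_that("crossover interval contains the planted splice for all PSV gaps", {
  set.seed(87)
  for (i in 1:50) {
    frame <- 3000
    psv_pos <- sort(sample(100:2900, 20))
    k <- sample(200:2800, 1)
    pp <- make_paralogs(frame, psv_pos, switch_at = k)
    below <- any(psv_pos <= k); above <- any(psv_pos > k)
    if (!below || !above) next  # splice outside the informative range
    cx <- map_crossover(pp$chimera, pp$a, pp$b)
    expect_lte(cx$switch_interval[1], k)
    expect_gte(cx$switch_interval[2], k + 1)
  }
})

test_that("PSV deserts degrade the call to an unresolvable interval", {
  set.seed(13)
  frame <- 20000
  psv_pos <- c(500, 1000, 10000, 19000)  # 9 kb gap around the switch
  pp <- make_paralogs(frame, psv_pos, switch_at = 5000)
  cx <- map_crossover(pp$chimera, pp$a, pp$b)
  expect_true(cx$unresolvable)
  expect_gt(cx$identity_block_len, 8000)
})

test_that("gene-conversion-like PSVs are secondary, runs open a new block", {
  set.seed(14)
  pp <- make_paralogs(2000, c(100, 400, 700, 1000, 1300, 1600, 1900),
                      switch_at = 1150)
  # isolated opposite-paralog PSV inside the A block
  cc <- strsplit(pp$chimera, "")[[1]]
  bc <- strsplit(pp$b, "")[[1]]
  cc[400] <- bc[400]
  cx <- map_crossover(paste0(cc, collapse = ""), pp$a, pp$b)
  expect_false(isTRUE(cx$multi_switch))
  expect_true(400 %in% cx$secondary$pos)
  # a run of >= 2 consecutive opposite-paralog PSVs inside the main block
  # cannot be explained by one switch: multi-switch report
  pp2 <- make_paralogs(3000, c(100, 400, 700, 1000, 1300, 1600, 1900,
                               2300, 2600), switch_at = 2100)
  cc2 <- strsplit(pp2$chimera, "")[[1]]
  bc2 <- strsplit(pp2$b, "")[[1]]
  cc2[700] <- bc2[700]; cc2[1000] <- bc2[1000]
  cx2 <- map_crossover(paste0(cc2, collapse = ""), pp2$a, pp2$b)
  expect_true(cx2$multi_switch)
  expect_setequal(cx2$secondary$pos, c(700, 1000))
})

test_that("PSV-specific PCR predicts the haplotype amplicon classes", {
  locus <- plp1_locus()
  h1 <- reference_allele(locus)
  h2 <- apply_inversion(locus)
  p1 <- predict_psv_pcr(h1)
  expect_equal(p1$present[p1$class %in% c("AA", "BB")], c(TRUE, TRUE))
  expect_equal(p1$present[p1$class %in% c("AB", "BA")], c(FALSE, FALSE))
  p2 <- predict_psv_pcr(h2)
  expect_equal(p2$present, c(FALSE, FALSE, TRUE, TRUE))
  # heterozygote = union of the two hemizygous predictions
  het <- predict_psv_pcr(list(h1, h2))
  expect_true(all(het$present))
  # allele carrying a single repeat copy yields exactly one class
  p <- xq22cgr:::pair_info(locus, "A")
  single <- new_cgr_allele(
    tibble::tibble(start = p$a1 - 5000, end = p$a2 + 5000, strand = "+"),
    locus = locus)
  ps <- predict_psv_pcr(single)
  expect_equal(sum(ps$present), 1)
  expect_true(ps$present[ps$class == "AA"])
  # primer offsets must be PSV-informative when a map is supplied
  pm <- tibble::tibble(pos = c(10, 20), a = c("A", "C"), b = c("G", "T"))
  expect_error(predict_psv_pcr(h1, forward_offset = 11, reverse_offset = 20,
                               psvs = pm), "not PSV-informative")
})

test_that("cloning plans tile both paralogs with unique anchors", {
  locus <- plp1_locus()
  plan <- plan_lcr_cloning(locus)
  expect_equal(nrow(plan), 4)
  expect_true(all(plan$length >= 12000 & plan$length <= 16000))
  expect_equal(sort(unique(plan$paralog)), c("A1a", "A1b"))
  # two amplicons per paralog overlap
  for (nm in c("A1a", "A1b")) {
    amps <- plan[plan$paralog == nm, ]
    expect_gte(min(amps$end) - max(amps$start), 1000)
  }
  plan10 <- plan_lcr_cloning(plp1_locus(0.1))
  expect_true(all(plan10$length >= 1200 & plan10$length <= 1600))
  # a repeat with no unique flank is rejected
  bad <- toy_locus()
  bad$repeats$end[bad$repeats$name == "A1a"] <- 1795
  bad$repeats$start[bad$repeats$name == "A1b"] <- 1795
  expect_error(plan_lcr_cloning(bad), "unique flank")
})
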