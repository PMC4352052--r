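test_that("the NAHR inversion is copy-neutral and an involution", {
  locus <- plp1_locus()
  h2 <- apply_inversion(locus, crossover = 5000)
  expect_equal(allele_length(h2), allele_length(reference_allele(locus)))
  prof <- copy_number_profile(h2)
  expect_equal(prof$state, 1)
  expect_equal(h2$provenance$haplotype, "H2")
  back <- apply_inversion(h2, crossover = 5000)
  expect_equal(back$segments, reference_allele(locus)$segments)
  expect_equal(nrow(back$junctions), 0)
  expect_error(apply_inversion(locus, crossover = 10^6),
               "outside the alignable repeat region")
})

test_that("inversion sequence equals the brute-force string construction", {
  locus <- toy_locus()
  cfg <- sim_config(seed = 11)
  ref <- make_locus_sequence(locus, cfg)$sequence
  u <- 60
  h2 <- apply_inversion(locus, crossover = u)
  got <- emit_sequence(h2, ref)
  # independent construction: prefix + revcomp(middle) + suffix
  xa <- 1000 + u; xb <- 2000 - u
  expected <- paste0(substr(ref, 1, xa),
                     revcomp(substr(ref, xa + 1, xb)),
                     substr(ref, xb + 1, nchar(ref)))
  expect_identical(got, expected)
  # involution at sequence level
  expect_identical(emit_sequence(apply_inversion(h2, crossover = u), ref), ref)
})

test_that("DUP-TRP/INV-DUP reproduces the published endpoint arithmetic", {
  locus <- plp1_locus()
  rec <- read_junction_table()
  for (i in seq_len(nrow(rec))) {
    al <- build_dup_trp_inv_dup(locus,
                                trp_start = from_printed(rec$trp_start[i]),
                                dup_start = from_printed(rec$dup_start[i]))
    sz <- size_arithmetic(al)
    expect_equal(sz$dup_size, rec$dup_size[i])
    if (is.na(rec$flags[i])) {
      expect_equal(sz$trp_size, rec$trp_size[i])
    } else {
      # one printed triplication size disagrees with its own endpoints by 2
      expect_equal(sz$trp_size, rec$trp_size[i] - 2)
    }
    tr <- profile_transitions(copy_number_profile(al, snap = TRUE))
    expect_equal(nrow(tr), 4)
    jm <- junction_multiset(al)
    expect_setequal(jm$label, c("Jct1", "Jct2"))
    expect_equal(jm$multiplicity, c(1L, 1L))
  }
})

test_that("DUP-TRP/INV-DUP rejects invalid orderings", {
  locus <- plp1_locus()
  expect_error(build_dup_trp_inv_dup(locus, trp_start = from_printed(103224000),
                                     dup_start = from_printed(102866025)),
               "ordering violation")
  expect_error(build_dup_trp_inv_dup(locus, trp_start = from_printed(102866025),
                                     dup_start = from_printed(103145195)),
               "ordering violation")
})

test_that("copy-number profiles equal brute-force per-base coverage", {
  set.seed(421)
  for (i in 1:200) {
    al <- random_toy_allele()
    prof <- copy_number_profile(al)
    expect_equal(tibble::tibble(start = prof$start, end = prof$end,
                                state = prof$state),
                 coverage_oracle(al))
  }
})

test_that("coverage conservation: extra profile mass equals extra segment bp", {
  set.seed(77)
  for (i in 1:50) {
    al <- random_toy_allele()
    prof <- copy_number_profile(al)
    extra_mass <- sum((prof$state - 1) * (prof$end - prof$start))
    extra_bp <- allele_length(al) -
      (al$locus$extent[2] - al$locus$extent[1])
    expect_equal(extra_mass, extra_bp)
  }
})

test_that("nested deletion drops copy number by one over the interval", {
  locus <- plp1_locus()
  al <- build_dup_trp_inv_dup(locus, trp_start = from_printed(103019045),
                              dup_start = from_printed(102803592))
  # 27 kb deletion on the direct duplicated copy (CN 2 -> 1)
  del <- c(from_printed(102850000), from_printed(102850000) + 27000)
  idx <- which(al$segments$start <= del[1] & al$segments$end >= del[2] &
                 al$segments$strand == "+")[1]
  del_al <- apply_nested_deletion(al, idx, del)
  prof <- copy_number_profile(del_al, snap = TRUE)
  state_in <- prof$state[prof$start <= del[1] & prof$end >= del[2]]
  expect_equal(state_in, 1)
  expect_equal(nrow(del_al$junctions), nrow(al$junctions) + 1)
  expect_error(apply_nested_deletion(al, idx, c(del[1], del[1])), "empty")
  expect_error(apply_nested_deletion(al, idx, c(0, 10)), "not contained")
})

test_that("rolling-circle traversal count sets the junction multiplicities", {
  locus <- plp1_locus()
  quad <- build_rolling_circle_quadruplication(
    locus, circle = c(102700000, 102980000),
    rolled_length = 2 * 280000 - 35000,
    termination_crossover = 102650000)
  expect_equal(junction_multiplicity(quad, "FoSTeS2/3"), 2L)
  expect_equal(junction_multiplicity(quad, "FoSTeS1"), 1L)
  prof <- copy_number_profile(quad)
  # 35 kb shortfall at CN 3, both-traversal region at CN 4
  expect_equal(prof$state, c(1, 2, 4, 3, 1))
  short <- prof[prof$state == 3, ]
  expect_equal(short$end - short$start, 35000)
  # exactly two full rolls: no CN-3 shortfall segment
  quad2 <- build_rolling_circle_quadruplication(
    locus, circle = c(102700000, 102980000), rolled_length = 2 * 280000,
    termination_crossover = 102650000)
  expect_false(any(copy_number_profile(quad2)$state == 3))
  expect_equal(junction_multiplicity(quad2, "FoSTeS2/3"), 2L)
  # sub-circle rolls are a plain tandem event, not an amplification
  expect_error(build_rolling_circle_quadruplication(
    locus, circle = c(102700000, 102980000), rolled_length = 100000,
    termination_crossover = 102650000), "tandem")
  expect_error(junction_multiplicity(quad, "nope"), "unknown junction label")
})

test_that("emitted sequences honor segment order and orientation", {
  locus <- toy_locus()
  ref <- make_locus_sequence(locus, sim_config(seed = 3))$sequence
  expect_identical(emit_sequence(reference_allele(locus), ref), ref)
  inv_seg <- new_cgr_allele(
    tibble::tibble(start = 100, end = 200, strand = "-"), locus = locus)
  expect_identical(emit_sequence(inv_seg, ref),
                   revcomp(substr(ref, 101, 200)))
  al <- build_event_allele_pub(locus, list(type = "dup_trp_inv_dup",
                                           trp_start = 800, dup_start = 300,
                                           jct1_crossover = 50))
  expect_equal(nchar(emit_sequence(al, ref)), allele_length(al))
  expect_error(emit_sequence(reference_allele(locus), substr(ref, 1, 10)),
               "shorter")
})

test_that("reconcile_structure identifies each grammar member uniquely", {
  locus <- plp1_locus()
  dtid <- build_dup_trp_inv_dup(locus, trp_start = from_printed(103088384),
                                dup_start = from_printed(102744808))
  res <- reconcile_structure(copy_number_profile(dtid, snap = TRUE),
                             junction_multiset(dtid), locus)
  expect_equal(res$model[which(res$consistent)], "dup_trp_inv_dup")
  quad <- build_rolling_circle_quadruplication(
    locus, circle = c(102700000, 102980000),
    rolled_length = 2 * 280000 - 35000, termination_crossover = 102650000)
  res_q <- reconcile_structure(copy_number_profile(quad, snap = TRUE),
                               junction_multiset(quad), locus)
  expect_equal(res_q$model[which(res_q$consistent)],
               "rolling_circle_quadruplication")
  two_step <- res_q[res_q$model == "two_step_recombination_quadruplication", ]
  expect_true(is.na(two_step$consistent))  # reported, not scored
  expect_match(two_step$note, "two events in separate generations")
  flat <- reconcile_structure(copy_number_profile(reference_allele(locus)),
                              junction_multiset(reference_allele(locus)),
                              locus)
  expect_equal(flat$model[which(flat$consistent)], "reference")
  expect_error(reconcile_structure(copy_number_profile(dtid)[0, ],
                                   junction_multiset(dtid), locus), "empty")
})

test_that("H2-progenitor products carry the polymorphic repeat junctions", {
  locus <- plp1_locus()
  al <- build_dup_trp_inv_dup(locus, trp_start = from_printed(103145195),
                              dup_start = from_printed(102866025),
                              progenitor = "H2")
  all_jn <- junction_multiset(al, event_only = FALSE)
  ev_jn <- junction_multiset(al)
  expect_setequal(ev_jn$label, c("Jct1", "Jct2"))
  expect_true(any(grepl("^inv_", all_jn$label)))
  # CN profile identical across progenitors
  al_h1 <- build_dup_trp_inv_dup(locus, trp_start = from_printed(103145195),
                                 dup_start = from_printed(102866025))
  expect_equal(copy_number_profile(al, snap = TRUE),
               copy_number_profile(al_h1, snap = TRUE))
})
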