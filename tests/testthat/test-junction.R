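test_that("published junction signatures are reproduced from sequence", {
  # microhomology "TTGA" planted in its printed context (-gagTTGActg-)
  core <- "gagTTGActg"
  left <- "ACCGTTAGCCATGGACCA"  # arbitrary unique flanks
  right <- "TGGTCACCTTGAACCGTA"
  q <- toupper(paste0(left, core, right))
  prox <- paste0(toupper(left), "GAGTTGA", "GGTGGTGGTGGTGGTGGTGGTGGTGGTGG")
  dist <- paste0("ATATATATATATATATATATATATATAT", "TTGACTG", toupper(right))
  cl <- call_junction(q, prox, dist)
  expect_equal(cl$microhomology, "TTGA")
  expect_false(cl$blunt)
  # blunt join (-ttgg/tctg-)
  qb <- toupper(paste0(left, "ttgg", "tctg", right))
  proxb <- paste0(toupper(left), "TTGG", "AAAAAAAAAAAAAAAAAAAAAAAAAA")
  distb <- paste0("GGGGGGGGGGGGGGGGGGGGGGGGGA", "TCTG", toupper(right))
  clb <- call_junction(qb, proxb, distb)
  expect_true(clb$blunt)
  expect_equal(clb$microhomology, "")
  # 47 bp of identity between paralogous elements
  pj <- plant_junction(n = 120, prefix = 80, ovl = 47)
  cl47 <- call_junction(pj$query, pj$prox, pj$dist)
  expect_equal(nchar(cl47$microhomology), 47)
})

test_that("caller equals the exhaustive split-point oracle on random cases", {
  set.seed(1234)
  for (i in 1:1000) {
    n <- sample(20:40, 1)
    ovl <- sample(-8:10, 1)
    pj <- plant_junction(n = n, ovl = ovl)
    cl <- call_junction(pj$query, pj$prox, pj$dist)
    or <- junction_oracle(pj$query, pj$prox, pj$dist)
    expect_equal(cl$prefix_match_len, or$prefix)
    expect_equal(cl$suffix_match_len, or$suffix)
    expect_equal(cl$microhomology, or$microhomology)
    expect_equal(cl$insertion, or$insertion)
    expect_equal(cl$blunt, or$blunt)
    # decomposition conservation
    expect_equal(cl$prefix_match_len + cl$suffix_match_len -
                   max(or$overlap, 0) + nchar(cl$insertion), n)
  }
})

test_that("reverse-complement symmetry mirrors the call", {
  set.seed(55)
  for (i in 1:25) {
    pj <- plant_junction(n = 40, ovl = sample(0:6, 1))
    cl <- call_junction(pj$query, pj$prox, pj$dist)
    mirrored <- call_junction(revcomp(pj$query), revcomp(pj$dist),
                              revcomp(pj$prox))
    expect_equal(mirrored$prefix_match_len, cl$suffix_match_len)
    expect_equal(mirrored$suffix_match_len, cl$prefix_match_len)
    expect_equal(mirrored$microhomology, revcomp(cl$microhomology))
  }
})

test_that("inverted distal templates are handled via orientation", {
  pj <- plant_junction(n = 60, prefix = 35, ovl = 4)
  cl_direct <- call_junction(pj$query, pj$prox, pj$dist)
  cl_inv <- call_junction(pj$query, pj$prox, revcomp(pj$dist),
                          dist_orientation = "inverted")
  expect_equal(tidy(cl_inv)[setdiff(names(tidy(cl_inv)), "distal_orientation")],
               tidy(cl_direct)[setdiff(names(tidy(cl_direct)),
                                       "distal_orientation")])
})

test_that("degenerate inputs are rejected with the right diagnosis", {
  expect_error(call_junction("ACGTACGTACGT", "ACGTACGTACGTACGT",
                             "ACGTACGTACGTACGT"), "shorter than 20")
  q <- random_dna_str(30)
  expect_error(call_junction(q, substr(q, 1, 10), q), "flanks shorter")
  expect_error(call_junction(q, q, paste0(random_dna_str(30))),
               "fully explained by one flank")
})

test_that("isolated mismatches extend matches and surface as mutations", {
  set.seed(9)
  pj <- plant_junction(n = 80, prefix = 60, ovl = 3)
  # plant a substitution 20 bp into the proximal match (offset 41 from switch)
  qc <- strsplit(pj$query, "")[[1]]
  qc[20] <- setdiff(c("A", "C", "G", "T"), qc[20])[1]
  qmut <- paste0(qc, collapse = "")
  cl0 <- call_junction(qmut, pj$prox, pj$dist, mismatch_budget = 0)
  expect_equal(cl0$prefix_match_len, 19)  # mismatch truncates without budget
  cl1 <- call_junction(qmut, pj$prox, pj$dist, mismatch_budget = 1)
  expect_equal(cl1$prefix_match_len, 60)
  expect_equal(nrow(cl1$mutations), 1)
  expect_equal(cl1$mutations$offset, 60 - 20 + 1)
  expect_equal(cl1$microhomology, nchar(cl1$microhomology) |>
                 (\(n) substr(qmut, 80 - cl1$suffix_match_len + 1, 60))())
})

test_that("de novo mutation flagging windows by distance from the switch", {
  set.seed(10)
  pj <- plant_junction(n = 300, prefix = 260, ovl = 2)
  qc <- strsplit(pj$query, "")[[1]]
  # offsets from the switch (position 260): 50 and 200
  for (pos in c(211, 61)) qc[pos] <- setdiff(c("A", "C", "G", "T"), qc[pos])[1]
  qmut <- paste0(qc, collapse = "")
  cl <- call_junction(qmut, pj$prox, pj$dist, mismatch_budget = 2)
  expect_equal(sort(cl$mutations$offset), c(50, 200))
  flagged <- flag_denovo_mutations(cl, window = 100)
  expect_equal(nrow(flagged), 1)
  expect_equal(flagged$offset, 50)
  clean <- call_junction(pj$query, pj$prox, pj$dist, mismatch_budget = 2)
  expect_equal(nrow(flag_denovo_mutations(clean, 100)), 0)
})

test_that("insertion templates are located on both strands", {
  set.seed(31)
  space <- random_dna_str(5000)
  ins93 <- substr(space, 1201, 1293)
  hits <- locate_insertion_template(ins93, space, search_offset = 102739000)
  expect_equal(nrow(hits), 1)
  expect_equal(hits$strand, "+")
  expect_equal(hits$position, 102739000 + 1201)
  ins57rc <- revcomp(substr(space, 3301, 3357))
  hits_rc <- locate_insertion_template(ins57rc, space, search_offset = 0)
  expect_equal(hits_rc$strand, "-")
  expect_equal(hits_rc$position, 3301)
  absent <- locate_insertion_template(strrep("AC", 15), space,
                                      max_mismatch = 0)
  expect_equal(nrow(absent), 0)
})

test_that("insertion-bearing junctions resolve into ordered switches", {
  set.seed(77)
  n <- 120
  # query = prox[1..50] + template (30 bp from the search space) + dist tail
  space <- random_dna_str(3000)
  template <- substr(space, 1001, 1030)
  proxpart <- random_dna_str(50)
  distpart <- random_dna_str(40)
  q <- paste0(proxpart, template, distpart)
  prox <- paste0(proxpart, flip_base(substr(template, 1, 1)),
                 random_dna_str(n))
  dist <- paste0(random_dna_str(n),
                 flip_base(substr(template, 30, 30)), distpart)
  cl <- call_junction(q, prox, dist)
  expect_equal(nchar(cl$insertion), 30)
  sw <- resolve_insertion(cl, space)
  expect_equal(nrow(sw), 1)
  expect_equal(sw$template_position, 1001)
  expect_equal(sw$template_strand, "+")
  expect_false(sw$uturn)
})

test_that("junction-table summarization matches the published cohort counts", {
  rec <- read_junction_table()
  s <- summarize_junction_table(rec)
  expect_equal(s$counts$n_records, 16)
  expect_equal(s$counts$n_microhomology, 14)
  expect_equal(s$counts$n_blunt, 2)
  # additional template switches in P500, P518, BAB1290, BAB2389
  expect_setequal(rec$patient[rec$has_template_insertion],
                  c("P500", "P518", "BAB1290", "BAB2389"))
  expect_setequal(rec$patient[rec$is_blunt], c("P558", "P842"))
  expect_setequal(rec$patient[rec$has_chimeric_element],
                  c("P518", "BAB3698"))
  # microhomology lengths cluster at 1-4 bp for single-switch junctions
  single <- rec[!rec$has_template_insertion & rec$has_microhomology &
                  !rec$has_chimeric_element, ]
  expect_true(all(unlist(single$microhomology_runs) <= 4))
  empty <- summarize_junction_table(rec[0, ])
  expect_equal(empty$counts$n_records, 0)
  expect_equal(empty$counts$mutation_rate_per_bp, 0)
})
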